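#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-category validation statistics
#'
#' @param x A `splice_validation` object.
#' @param ... Unused.
#' @return A tibble with one row per variant x carrier sample x evidence
#'   category: observed count, control `mu`/`sigma`, `z`, the
#'   Yeo-Johnson-transformed `psi_z`, the one-sided `p`, and the
#'   `significant`/`strong` flags that drive validation.
#' @exportS3Method generics::tidy
tidy.splice_validation <- function(x, ...) {
  x$results
}

#' One-row summary of a validation run
#'
#' @param x A `splice_validation` object.
#' @param ... Unused.
#' @return A one-row tibble: numbers of variants, validated variants,
#'   carrier results, control samples, and the run's `alpha` and `lambda`.
#' @exportS3Method generics::glance
glance.splice_validation <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x$variants),
    n_validated = sum(x$variants$validated),
    n_experimental = dplyr::n_distinct(x$results$sample_id),
    n_controls = if (nrow(x$results) > 0) max(x$results$n_controls) else 0L,
    alpha = x$config$alpha,
    lambda = x$config$lambda
  )
}

#' @export
print.splice_validation <- function(x, ...) {
  g <- glance(x)
  cat("<splice_validation>\n")
  cat(sprintf("  %d variant(s); %d validated at p < %g\n",
              g$n_variants, g$n_validated, g$alpha))
  cat(sprintf("  %d carrier sample(s); up to %d controls per variant\n",
              g$n_experimental, g$n_controls))
  if (nrow(x$results) > 0) {
    sig <- x$results |>
      dplyr::filter(.data$significant, .data$strong) |>
      dplyr::select(dplyr::all_of(c("variant_id", "sample_id", "category",
                                    "observed", "p")))
    if (nrow(sig) > 0) {
      cat("  significant strong-category results:\n")
      out <- utils::capture.output(print(as.data.frame(sig), row.names = FALSE))
      cat(paste0("  ", out, collapse = "\n"), "\n")
    }
  }
  invisible(x)
}
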