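#' Type-8 sample quantile
#'
#' The median-unbiased quantile estimator (plotting position
#' `h = (n + 1/3) p + 1/3` with linear interpolation between order
#' statistics), the variant recommended by Hyndman and Fan and used for the
#' Q-Q diagnostics of control read-count distributions.
#'
#' @param data Numeric vector (need not be sorted).
#' @param p Probabilities in `[0, 1]` (vectorized).
#' @return Numeric vector of quantiles, clamped to the data range.
#' @examples
#' quantile_type8(c(1, 2, 3, 4), 0.5)  # 2.5
#' @export
quantile_type8 <- function(data, p) {
  stopifnot(length(data) > 0, !anyNA(data), all(p >= 0 & p <= 1))
  x <- sort(data)
  n <- length(x)
  h <- (n + 1 / 3) * p + 1 / 3
  h <- pmin(pmax(h, 1), n)
  lo <- floor(h)
  hi <- pmin(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

#' Freedman-Diaconis histogram bin width
#'
#' `2 * IQR * n^(-1/3)` with the interquartile range computed from Type-8
#' quantiles ([quantile_type8()]). Degenerate data (fewer than two distinct
#' values, or zero IQR) fall back to a single bin spanning the data, with a
#' message.
#'
#' @param data Numeric vector.
#' @return Positive bin width.
#' @export
fd_bin_width <- function(data) {
  stopifnot(length(data) > 0, !anyNA(data))
  iqr <- diff(quantile_type8(data, c(0.25, 0.75)))
  width <- 2 * iqr * length(data)^(-1 / 3)
  if (!is.finite(width) || width <= 0) {
    message("fd_bin_width(): degenerate data; falling back to a single bin")
    width <- max(diff(range(data)), 1)
  }
  width
}

#' Histogram of control counts with embedded Q-Q plot
#'
#' Draws the control read-count distribution for one evidence category with
#' Freedman-Diaconis breaks, marks each observed (carrier) count with an
#' arrowhead labelled by sample and annotated with its p-value, and embeds
#' a normal Q-Q inset of the (optionally Yeo-Johnson transformed) control
#' counts using Type-8 quantiles. Statistically significant observations
#' are drawn in red.
#'
#' @param control_counts Numeric vector of per-control-sample counts.
#' @param observed Tibble/data frame with columns `label`, `count` and `p`
#'   (`p` may be `NA`); may have zero rows.
#' @param category Category label for the title.
#' @param transformed Plot Yeo-Johnson transformed counts instead of raw
#'   counts (default raw).
#' @param lambda Transform exponent used when `transformed = TRUE` and in
#'   the Q-Q inset.
#' @param alpha Significance threshold for red highlighting.
#' @return A patchwork/ggplot object; print or [ggplot2::ggsave()] it.
#' @export
plot_control_histogram <- function(control_counts, observed = NULL,
                                   category = "validated reads",
                                   transformed = FALSE, lambda = 0.5,
                                   alpha = 0.05) {
  stopifnot(is.numeric(control_counts), length(control_counts) > 0)
  values <- if (transformed) yeo_johnson(control_counts, lambda) else control_counts
  df <- tibble::tibble(count = values)
  width <- fd_bin_width(values)
  xlab <- if (transformed) {
    sprintf("Yeo-Johnson(count, lambda = %g) per control sample", lambda)
  } else {
    "validated reads per control sample"
  }
  hist <- ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(
      binwidth = width,
      boundary = 0, closed = "left",
      fill = "grey70", colour = "grey30", linewidth = 0.2
    ) +
    ggplot2::labs(
      title = category,
      x = xlab, y = "control samples"
    ) +
    ggplot2::theme_classic(base_size = 11)

  if (!is.null(observed) && nrow(observed) > 0) {
    stopifnot(all(c("label", "count", "p") %in% names(observed)),
              !anyDuplicated(observed$label))
    obs <- tibble::as_tibble(observed) |>
      dplyr::mutate(
        x = if (transformed) yeo_johnson(.data$count, lambda) else .data$count,
        sig = !is.na(.data$p) & .data$p < alpha,
        colour = dplyr::if_else(.data$sig, "red", "black"),
        p_label = format_p_display(.data$p)
      )
    ymax <- max(graphics::hist(values, plot = FALSE,
                               breaks = seq(min(values),
                                            max(values) + width,
                                            by = width))$counts)
    hist <- hist +
      ggplot2::geom_segment(
        data = obs,
        ggplot2::aes(x = .data$x, xend = .data$x,
                     y = 0.22 * ymax, yend = 0.04 * ymax),
        colour = obs$colour,
        arrow = ggplot2::arrow(length = ggplot2::unit(2.2, "mm"),
                               type = "closed"),
        inherit.aes = FALSE
      ) +
      ggplot2::geom_text(
        data = obs,
        ggplot2::aes(x = .data$x, y = 0.26 * ymax, label = .data$label),
        colour = obs$colour, size = 3, vjust = 0, inherit.aes = FALSE
      ) +
      ggplot2::labs(caption = paste(
        sprintf("%s: p = %s", obs$label, obs$p_label),
        collapse = "   "
      )) +
      ggplot2::theme(plot.caption = ggplot2::element_text(
        colour = if (any(obs$sig)) "red" else "black"
      ))
  }

  qq_vals <- yeo_johnson(control_counts, lambda)
  pp <- stats::ppoints(length(qq_vals))
  qq_df <- tibble::tibble(
    theoretical = stats::qnorm(pp),
    sample = quantile_type8(qq_vals, pp)
  )
  qq <- ggplot2::ggplot(qq_df,
                        ggplot2::aes(x = .data$theoretical, y = .data$sample)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::geom_qq_line(
      data = tibble::tibble(s = qq_vals),
      ggplot2::aes(sample = .data$s), inherit.aes = FALSE,
      colour = "grey40", linewidth = 0.3
    ) +
    ggplot2::labs(x = "normal quantiles", y = "YJ counts") +
    ggplot2::theme_classic(base_size = 7)

  hist + patchwork::inset_element(qq, left = 0.55, bottom = 0.55,
                                  right = 0.99, top = 0.99)
}

#' Plot control distribution and carrier counts for one validated category
#'
#' @param object A `splice_validation` object.
#' @param variant_id Which variant to plot (default: the first).
#' @param category Evidence category (default `"ii_ra"`).
#' @param transformed,... Passed to [plot_control_histogram()].
#' @return A patchwork/ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.splice_validation <- function(object, variant_id = NULL,
                                       category = "ii_ra",
                                       transformed = FALSE, ...) {
  stopifnot(category %in% stat_categories())
  if (is.null(variant_id)) variant_id <- object$counts$variant_id[1]
  ctl <- object$counts |>
    dplyr::filter(.data$variant_id == !!variant_id, .data$role == "control")
  res <- object$results |>
    dplyr::filter(.data$variant_id == !!variant_id,
                  .data$category == !!category)
  observed <- tibble::tibble(
    label = res$sample_id, count = res$observed, p = res$p
  )
  plot_control_histogram(
    ctl[[category]], observed,
    category = sprintf("%s - %s", variant_id, category),
    transformed = transformed, alpha = object$config$alpha, ...
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
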