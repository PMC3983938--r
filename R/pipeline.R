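stat_categories <- function() c("cs_js", "cs_ra", "es_js", "ii_js", "ii_jswm", "ii_ra")

strong_categories <- function() c("cs_js", "es_js", "ii_js", "ii_ra")

#' Read a BAM list file
#'
#' One alignment file per line; either a bare path or a
#' `directory/filename.bam` pair (e.g. archive UUID followed by the file
#' name). Relative entries are resolved against the list file's directory.
#' The sample id is the file name without its `.bam` extension.
#'
#' @param path Path to the list file.
#' @return A tibble with `sample_id` and `path`.
#' @export
read_bam_list <- function(path) {
  lines <- trimws(readr::read_lines(path))
  lines <- lines[nzchar(lines)]
  base <- dirname(path)
  resolved <- vapply(lines, function(p) {
    if (file.exists(p)) p
    else file.path(base, p)
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    sample_id = sub("\\.bam$", "", basename(lines)),
    path = resolved
  )
}

as_sample_table <- function(x, what = "samples") {
  if (is.null(x)) {
    return(tibble::tibble(sample_id = character(), path = character()))
  }
  if (is.character(x) && length(x) == 1L && !grepl("\\.bam$", x) &&
      file.exists(x)) {
    return(read_bam_list(x))
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sub("\\.bam$", "", basename(x))
    return(tibble::tibble(sample_id = ids, path = unname(x)))
  }
  stopifnot(is.data.frame(x), all(c("sample_id", "path") %in% names(x)))
  tibble::as_tibble(x[, c("sample_id", "path")])
}

#' Partition a cohort into carriers and controls for one variant
#'
#' The variant's carrier samples (from its `sample_ids` field) form the
#' experimental group; every other experimental-class sample plus all normal
#' samples form the control group. A recurrent variant with several carriers
#' therefore never has a carrier inside its own control group.
#'
#' @param variant One-row variant tibble (with `sample_ids`).
#' @param experimental Sample table (`sample_id`, `path`) of
#'   experimental-class (e.g. tumour) samples.
#' @param normals Sample table of normal samples (may be empty).
#' @return A list with tibbles `experimental` and `controls`, or `NULL`
#'   when no carrier is present among the provided samples.
#' @export
partition_cohort <- function(variant, experimental, normals = NULL) {
  normals <- as_sample_table(normals)
  experimental <- as_sample_table(experimental)
  carriers <- variant$sample_ids[[1]]
  exp_rows <- experimental |> dplyr::filter(.data$sample_id %in% carriers)
  if (nrow(exp_rows) == 0L) {
    return(NULL)
  }
  controls <- dplyr::bind_rows(
    experimental |> dplyr::filter(!.data$sample_id %in% carriers),
    normals
  )
  list(experimental = exp_rows, controls = controls)
}

#' Validate predicted splicing mutations against RNA-Seq cohorts
#'
#' The main entry point. For every variant: resolves splice contexts on all
#' isoforms of its gene, partitions the cohort into carriers and controls,
#' tallies evidence-category read counts in every sample, and tests each
#' carrier's count against the control distribution with a one-sided
#' Yeo-Johnson z-test ([splice_p_value()]). p-values are only attached to
#' consequence-by-evidence categories (e.g. junction-spanning exon
#' skipping), never to a bare consequence total.
#'
#' A variant is `validated` when any carrier reaches `p < alpha` in a
#' strongly corroborating category: the junction-spanning consequences
#' (cryptic, exon skipping, intron inclusion) or read-abundance total
#' intron inclusion.
#'
#' @param variants Variant tibble from [read_splice_variants()], or a path.
#' @param annotation Annotation tibble from [read_refgene()], or a path.
#' @param experimental Experimental-class samples: a BAM list file path, a
#'   (optionally named) character vector of BAM paths, or a tibble with
#'   `sample_id` and `path`.
#' @param normals Normal samples, same forms; optional.
#' @param alpha Significance threshold for validation (default 0.05).
#' @param lambda Yeo-Johnson exponent (default 1/2).
#' @param yj_mode `"zscore"` (transform the z statistic; default) or
#'   `"counts"` (transform the per-sample counts before standardizing).
#' @param min_mapq Minimum read mapping quality (default 1).
#' @param max_read_len Fetch-window padding in bp (default 1000).
#' @param strict_cryptic_split See [classify_reads()].
#' @param verbose Print per-variant progress.
#' @return A `splice_validation` object: a list with `variants` (input rows
#'   plus `validated`), `results` (tidy per variant x carrier x category
#'   statistics), `counts` (per variant x sample category counts, carriers
#'   and controls), `log` (character), and `config`. Has [tidy()],
#'   [glance()], `autoplot()` and `print()` methods.
#' @export
validate_splice_variants <- function(variants, annotation, experimental,
                                     normals = NULL,
                                     alpha = 0.05, lambda = 0.5,
                                     yj_mode = c("zscore", "counts"),
                                     min_mapq = 1L, max_read_len = 1000L,
                                     strict_cryptic_split = TRUE,
                                     verbose = FALSE) {
  yj_mode <- match.arg(yj_mode)
  stopifnot(alpha > 0, alpha < 1)
  if (is.character(variants)) variants <- read_splice_variants(variants)
  if (is.character(annotation)) annotation <- read_refgene(annotation)
  experimental <- as_sample_table(experimental)
  normals <- as_sample_table(normals)
  log_lines <- character()
  log_add <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    if (verbose) message(sprintf(...))
  }
  log_add("run started: %d variant(s), %d experimental sample(s), %d normal sample(s)",
          nrow(variants), nrow(experimental), nrow(normals))
  if (nrow(experimental) > 0 &&
      (nrow(experimental) + nrow(normals) - 1) < 5 * 1) {
    log_add("warning: fewer than 5 control samples per experimental sample; statistics will be weak")
  }

  all_results <- list()
  all_counts <- list()
  validated <- logical(nrow(variants))

  for (vi in seq_len(nrow(variants))) {
    v <- variants[vi, ]
    ctxs <- splice_contexts(v, annotation, max_read_len = max_read_len)
    for (s in attr(ctxs, "skipped")) log_add("context skipped: %s", s)
    if (nrow(ctxs) == 0L) {
      log_add("variant %s: no resolvable splice context on any isoform; skipped",
              v$variant_id)
      next
    }
    if (any(ctxs$generalized)) {
      log_add("variant %s: direction resolved by the generalized into-the-intron rule for (%s, %s)",
              v$variant_id, v$region, v$site_kind)
    }
    cohort <- partition_cohort(v, experimental, normals)
    if (is.null(cohort)) {
      log_add("variant %s skipped: no carrier among the provided experimental samples",
              v$variant_id)
      next
    }
    w_start <- min(ctxs$window_start)
    w_end <- max(ctxs$window_end)
    chrom <- ctxs$chromosome[1]
    pos0 <- ctxs$variant_pos0[1]

    count_sample <- function(sample_id, path) {
      reads <- fetch_reads(path, chrom, w_start, w_end,
                           variant_pos0 = pos0, min_mapq = min_mapq)
      count_region(reads, ctxs, sample_id = sample_id,
                   strict_cryptic_split = strict_cryptic_split)
    }
    exp_counts <- purrr::pmap(cohort$experimental, function(sample_id, path)
      count_sample(sample_id, path)) |> dplyr::bind_rows()
    ctl_counts <- purrr::pmap(cohort$controls, function(sample_id, path)
      count_sample(sample_id, path)) |> dplyr::bind_rows()

    low_cov <- exp_counts$sample_id[exp_counts$total_reads < 20]
    for (s in low_cov) {
      log_add("variant %s sample %s: coverage advisory (< 20 reads at locus)",
              v$variant_id, s)
    }
    if (nrow(ctl_counts) > 0 && sum(ctl_counts$total_reads) == 0) {
      log_add("variant %s: no reads in any control sample at the locus; insufficient coverage",
              v$variant_id)
    }

    res <- tidyr::expand_grid(
      sample_id = exp_counts$sample_id,
      category = stat_categories()
    ) |>
      purrr::pmap(function(sample_id, category) {
        obs <- exp_counts[[category]][exp_counts$sample_id == sample_id]
        splice_p_value(obs, ctl_counts[[category]], lambda = lambda,
                       category = category, yj_mode = yj_mode) |>
          dplyr::mutate(sample_id = sample_id)
      }) |>
      dplyr::bind_rows() |>
      dplyr::mutate(
        variant_id = v$variant_id,
        gene = v$gene,
        strong = .data$category %in% strong_categories(),
        significant = !is.na(.data$p) & .data$p < alpha,
        .before = 1
      )
    validated[vi] <- any(res$significant & res$strong)
    log_add("variant %s: %d carrier(s), %d control(s), validated = %s",
            v$variant_id, nrow(exp_counts), nrow(ctl_counts), validated[vi])

    all_results[[length(all_results) + 1L]] <- res
    all_counts[[length(all_counts) + 1L]] <- dplyr::bind_rows(
      exp_counts |> dplyr::mutate(role = "experimental"),
      ctl_counts |> dplyr::mutate(role = "control")
    ) |> dplyr::mutate(variant_id = v$variant_id, gene = v$gene, .before = 1)
  }

  log_add("run finished: %d of %d variant(s) validated",
          sum(validated), nrow(variants))
  structure(
    list(
      variants = variants |> dplyr::mutate(validated = validated),
      results = dplyr::bind_rows(all_results),
      counts = dplyr::bind_rows(all_counts),
      log = log_lines,
      config = list(
        alpha = alpha, lambda = lambda, yj_mode = yj_mode,
        min_mapq = min_mapq, max_read_len = max_read_len,
        strict_cryptic_split = strict_cryptic_split
      )
    ),
    class = "splice_validation"
  )
}

#' Keep only validated variants
#'
#' A variant is kept when at least one carrier sample has a defined
#' `p < alpha` in a strongly corroborating category (junction-spanning
#' cryptic splicing, exon skipping, or intron inclusion; read-abundance
#' total intron inclusion). The comparison is strict: `p` exactly equal to
#' `alpha` is not kept.
#'
#' @param x A `splice_validation` object.
#' @return The validated subset of the input variant tibble.
#' @export
filter_validated <- function(x) {
  stopifnot(inherits(x, "splice_validation"))
  x$variants |> dplyr::filter(.data$validated)
}

format_p_display <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "N/A",
    p < 0.005 ~ "< 0.01",
    TRUE ~ sprintf("%.2f", p)
  )
}

#' Write the validation output file set
#'
#' Produces, under `dir`:
#' * `experimental_counts.tsv` — per carrier sample, per category counts
#'   with the p-value in parentheses (`N/A` where undefined, `< 0.01` below
#'   the display threshold);
#' * `control_counts.tsv` — per control sample category counts;
#' * `control_summary.tsv` — per variant control totals and per-sample
#'   means;
#' * `results.tsv` — every statistic at full precision (machine-readable);
#' * `validated_variants.tsv` — the filtered variant file, in the input
#'   dialect;
#' * `summary.txt` — run progress/summary;
#' * `validation.log` — the per-variant run log.
#'
#' @param x A `splice_validation` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_validation <- function(x, dir) {
  stopifnot(inherits(x, "splice_validation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- c(
    experimental = file.path(dir, "experimental_counts.tsv"),
    controls = file.path(dir, "control_counts.tsv"),
    control_summary = file.path(dir, "control_summary.tsv"),
    results = file.path(dir, "results.tsv"),
    filtered = file.path(dir, "validated_variants.tsv"),
    summary = file.path(dir, "summary.txt"),
    log = file.path(dir, "validation.log")
  )

  exp_counts <- x$counts |> dplyr::filter(.data$role == "experimental")
  if (nrow(exp_counts) > 0) {
    p_of <- function(variant_id, sample_id, category) {
      m <- x$results$variant_id == variant_id &
        x$results$sample_id == sample_id & x$results$category == category
      if (any(m)) format_p_display(x$results$p[m][1]) else "N/A"
    }
    exp_tbl <- exp_counts |>
      dplyr::rowwise() |>
      dplyr::mutate(
        CS_JS = sprintf("%d (%s)", .data$cs_js, p_of(.data$variant_id, .data$sample_id, "cs_js")),
        CS_RA = sprintf("%d (%s)", .data$cs_ra, p_of(.data$variant_id, .data$sample_id, "cs_ra")),
        ES_JS = sprintf("%d (%s)", .data$es_js, p_of(.data$variant_id, .data$sample_id, "es_js")),
        II_JS = sprintf("%d (%s)", .data$ii_js, p_of(.data$variant_id, .data$sample_id, "ii_js")),
        II_JSwM = sprintf("%d (%s)", .data$ii_jswm, p_of(.data$variant_id, .data$sample_id, "ii_jswm")),
        II_RA = sprintf("%d (%s)", .data$ii_ra, p_of(.data$variant_id, .data$sample_id, "ii_ra")),
        II_total = as.character(.data$ii_total),
        normal_splice_reads = .data$normal_splice,
        anti_cryptic_reads = .data$anti_cryptic
      ) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(c(
        "variant_id", "gene", "sample_id", "CS_JS", "CS_RA", "ES_JS",
        "II_JS", "II_JSwM", "II_RA", "II_total", "normal_splice_reads",
        "anti_cryptic_reads", "read_fraction", "total_reads"
      )))
  } else {
    exp_tbl <- tibble::tibble()
  }
  readr::write_tsv(exp_tbl, paths["experimental"], progress = FALSE)

  ctl <- x$counts |> dplyr::filter(.data$role == "control")
  readr::write_tsv(
    ctl |> dplyr::select(-dplyr::any_of("role")),
    paths["controls"], progress = FALSE
  )
  ctl_summary <- ctl |>
    dplyr::group_by(.data$variant_id, .data$gene) |>
    dplyr::summarise(
      dplyr::across(
        dplyr::all_of(c(stat_categories(), "ii_total", "normal_splice")),
        list(total = sum, mean = mean)
      ),
      n_controls = dplyr::n(),
      .groups = "drop"
    )
  readr::write_tsv(ctl_summary, paths["control_summary"], progress = FALSE)

  readr::write_tsv(x$results, paths["results"], progress = FALSE)
  write_splice_variants(filter_validated(x), paths["filtered"])

  g <- glance(x)
  summary_lines <- c(
    "splice validation run summary",
    sprintf("variants analyzed: %d", g$n_variants),
    sprintf("variants validated (p < %g in a strong category): %d",
            x$config$alpha, g$n_validated),
    sprintf("experimental samples scored: %d", g$n_experimental),
    sprintf("control samples per variant (max): %d", g$n_controls),
    sprintf("yj_mode = %s, lambda = %g, min_mapq = %d",
            x$config$yj_mode, x$config$lambda, x$config$min_mapq)
  )
  readr::write_lines(summary_lines, paths["summary"])
  readr::write_lines(x$log, paths["log"])
  invisible(paths)
}
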