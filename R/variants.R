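#' Read a predicted splice-variant table
#'
#' The variant file is tab-delimited with a header and at least the columns
#' below (extra columns are kept untouched):
#'
#' * `chrom` — chromosome name;
#' * `pos` — 1-based genomic coordinate of the DNA change;
#' * `ref`, `alt` — single-base alleles;
#' * `gene` — gene symbol matching the annotation's `name2`;
#' * `strand` — `+` or `-`;
#' * `site_kind` — `donor` or `acceptor`, the natural splice site affected;
#' * `region` — `exonic` or `intronic`, where the variant lies;
#' * `class` — `natural` (weakens/inactivates the natural site) or
#'   `cryptic` (activates a non-constitutive site);
#' * `initial_ri`, `final_ri` — individual-information strength of the site
#'   in bits before/after the mutation (consumed as given, never computed);
#' * `cryptic_pos` — 1-based coordinate of the predicted cryptic splice
#'   junction, interpreted as the first base after the junction boundary;
#'   `.` or empty for non-cryptic variants;
#' * `samples` — comma-separated ids of the experimental samples whose
#'   exomes carry the variant.
#'
#' @param path Path to the file, or a character vector of lines.
#' @return A tibble, one row per variant, with a `delta_ri` column
#'   (`final_ri - initial_ri`, bits), a parsed `sample_ids` list-column, and
#'   a `variant_id` key (`chrom:pos ref>alt`).
#' @export
read_splice_variants <- function(path) {
  txt <- if (length(path) == 1L && file.exists(path)) {
    readr::read_lines(path)
  } else {
    path
  }
  required <- c(
    "chrom", "pos", "ref", "alt", "gene", "strand", "site_kind", "region",
    "class", "initial_ri", "final_ri", "cryptic_pos", "samples"
  )
  header <- strsplit(txt[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(required, header)
  if (length(missing) > 0L) {
    stop("variant file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  v <- readr::read_tsv(
    I(paste(txt, collapse = "\n")),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      gene = readr::col_character(),
      strand = readr::col_character(),
      site_kind = readr::col_character(),
      region = readr::col_character(),
      class = readr::col_character(),
      initial_ri = readr::col_double(),
      final_ri = readr::col_double(),
      cryptic_pos = readr::col_character(),
      samples = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  validate_variants(v)
  v |>
    dplyr::mutate(
      cryptic_pos = suppressWarnings(as.integer(
        dplyr::if_else(.data$cryptic_pos %in% c(".", "", "NA"),
                       NA_character_, .data$cryptic_pos)
      )),
      delta_ri = .data$final_ri - .data$initial_ri,
      sample_ids = purrr::map(
        .data$samples,
        ~ setdiff(trimws(strsplit(.x %||% "", ",")[[1]]), "")
      ),
      variant_id = sprintf("%s:%d%s>%s", .data$chrom, .data$pos,
                           .data$ref, .data$alt)
    )
}

validate_variants <- function(v) {
  bad_allele <- !v$ref %in% c("A", "C", "G", "T") |
    !v$alt %in% c("A", "C", "G", "T")
  if (any(bad_allele)) {
    stop("variant row(s) ", paste(which(bad_allele), collapse = ", "),
         ": ref/alt alleles must be single bases A/C/G/T")
  }
  bad_enum <- !v$site_kind %in% c("donor", "acceptor") |
    !v$region %in% c("exonic", "intronic") |
    !v$class %in% c("natural", "cryptic") |
    !v$strand %in% c("+", "-")
  if (any(bad_enum)) {
    stop("variant row(s) ", paste(which(bad_enum), collapse = ", "),
         ": invalid site_kind/region/class/strand value")
  }
  no_jc <- v$class == "cryptic" &
    (is.na(v$cryptic_pos) | v$cryptic_pos %in% c(".", ""))
  if (any(no_jc)) {
    stop("variant row(s) ", paste(which(no_jc), collapse = ", "),
         ": cryptic variants must provide cryptic_pos")
  }
  invisible(v)
}

#' Write a splice-variant table in the input dialect
#'
#' Used for the filtered validated-variant output so that downstream tools
#' can consume it with [read_splice_variants()] unchanged.
#'
#' @param variants Tibble of variants (as read, possibly subset).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splice_variants <- function(variants, path) {
  out <- variants |>
    dplyr::select(-dplyr::any_of(c("delta_ri", "sample_ids", "variant_id"))) |>
    dplyr::mutate(cryptic_pos = dplyr::if_else(
      is.na(.data$cryptic_pos), ".", as.character(.data$cryptic_pos)
    ))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
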