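#' Direction in which reads are checked for a variant
#'
#' The checking direction points from the affected natural splice junction
#' into the adjacent intron whose splicing the variant perturbs. For the two
#' canonical cases this is the published lookup: an exonic variant at a donor
#' is checked rightwards on `+` (leftwards on `-`), and an intronic variant
#' at an acceptor leftwards on `+` (rightwards on `-`). The remaining
#' (region, site) combinations follow the same into-the-intron rule and are
#' flagged as generalized so the run log can note them.
#'
#' @param region `"exonic"` or `"intronic"` (vectorized).
#' @param site_kind `"donor"` or `"acceptor"`.
#' @param strand `"+"` or `"-"`.
#' @param generalize If `FALSE`, combinations outside the two canonical rows
#'   raise a "direction undefined" error instead of being generalized.
#' @return Character vector, `"left"` or `"right"`, with attribute
#'   `generalized` (logical vector).
#' @examples
#' resolve_direction("exonic", "donor", "+")      # right
#' resolve_direction("intronic", "acceptor", "+") # left
#' @export
resolve_direction <- function(region, site_kind, strand, generalize = TRUE) {
  n <- max(length(region), length(site_kind), length(strand))
  region <- rep_len(region, n)
  site_kind <- rep_len(site_kind, n)
  strand <- rep_len(strand, n)
  stopifnot(
    all(region %in% c("exonic", "intronic")),
    all(site_kind %in% c("donor", "acceptor")),
    all(strand %in% c("+", "-"))
  )
  canonical <- (region == "exonic" & site_kind == "donor") |
    (region == "intronic" & site_kind == "acceptor")
  if (!generalize && any(!canonical)) {
    i <- which(!canonical)[1]
    stop(sprintf(
      "direction undefined for (region = %s, site_kind = %s, strand = %s)",
      region[i], site_kind[i], strand[i]
    ))
  }
  # donor: intron lies 3' of the junction; acceptor: 5'. Genomic left/right
  # then depends only on strand.
  dir <- ifelse(
    site_kind == "donor",
    ifelse(strand == "+", "right", "left"),
    ifelse(strand == "+", "left", "right")
  )
  attr(dir, "generalized") <- !canonical
  dir
}

#' Resolve splice-context coordinates for one variant on one transcript
#'
#' Locates the natural splice junction `A` affected by the variant, the next
#' natural junction `B` across the adjacent intron (in the checking
#' direction), the skip-junction endpoints `D`/`E` (the inner boundaries of
#' the exons flanking the variant-associated exon), the cryptic junction
#' `J` when the variant activates a cryptic site, and the differential
#' region between `J` and `A` whose splicing status distinguishes the
#' cryptic from the normal isoform.
#'
#' All coordinates in the returned row are 0-based junction/boundary
#' positions (the position of the first base after the boundary), matching
#' the half-open exon intervals of [read_refgene()].
#'
#' @param variant A one-row tibble / named list from
#'   [read_splice_variants()].
#' @param transcript A one-row tibble from [read_refgene()].
#' @param max_read_len Padding added on both sides of the fetch window so
#'   that reads merely overlapping the region are retrieved (default 1000).
#' @return A one-row tibble (`variant_id`, `transcript_id`, `gene_symbol`,
#'   `chromosome`, `strand`, `direction`, `generalized`, `A`, `B`, `D`, `E`,
#'   `J`, `intron_start`, `intron_end`, `diff_lo`, `diff_hi`, `diff_mode`,
#'   `window_start`, `window_end`, `variant_pos0`, `alt_allele`,
#'   `is_cryptic`), or a zero-row tibble with attribute `reason` when no
#'   context exists on this transcript (variant outside its span, stated
#'   region inconsistent with the exon structure, or no intron on the
#'   checking side).
#' @export
build_splice_context <- function(variant, transcript, max_read_len = 1000L) {
  v <- as.list(variant)
  tx <- as.list(transcript)
  no_context <- function(reason) {
    out <- tibble::tibble()
    attr(out, "reason") <- reason
    out
  }
  exons <- tx$exons[[1]]
  n <- nrow(exons)
  pos0 <- v$pos - 1L
  if (pos0 < tx$tx_start || pos0 >= tx$tx_end) {
    return(no_context("variant outside transcript span"))
  }
  exon_idx <- which(exons[, "start"] <= pos0 & pos0 < exons[, "end"])

  if (v$region == "exonic") {
    if (length(exon_idx) == 0L) {
      return(no_context("variant declared exonic but falls in an intron of this isoform"))
    }
    s_idx <- exon_idx[1]
    A <- if (v$site_kind == "donor") {
      if (v$strand == "+") exons[s_idx, "end"] else exons[s_idx, "start"]
    } else {
      if (v$strand == "+") exons[s_idx, "start"] else exons[s_idx, "end"]
    }
  } else {
    if (length(exon_idx) > 0L) {
      return(no_context("variant declared intronic but falls in an exon of this isoform"))
    }
    i <- findInterval(pos0, exons[, "end"])
    if (i < 1L || i >= n) {
      return(no_context("variant not inside any intron of this isoform"))
    }
    # affected site of the containing intron; the variant-associated exon is
    # the exon on the exonic side of that site
    if (v$site_kind == "donor") {
      if (v$strand == "+") { A <- exons[i, "end"]; s_idx <- i }
      else { A <- exons[i + 1L, "start"]; s_idx <- i + 1L }
    } else {
      if (v$strand == "+") { A <- exons[i + 1L, "start"]; s_idx <- i + 1L }
      else { A <- exons[i, "end"]; s_idx <- i }
    }
  }

  dir <- resolve_direction(v$region, v$site_kind, v$strand)
  generalized <- attr(dir, "generalized")[1]
  dir <- as.character(dir)

  # the intron adjacent to A on the checking side
  if (dir == "right") {
    j <- which(exons[, "end"] == A)
    if (length(j) == 0L || j >= n) {
      return(no_context("no intron on the checking side of the natural junction"))
    }
    intron_start <- A
    intron_end <- exons[j + 1L, "start"]
    B <- intron_end
  } else {
    j <- which(exons[, "start"] == A)
    if (length(j) == 0L || j <= 1L) {
      return(no_context("no intron on the checking side of the natural junction"))
    }
    intron_end <- A
    intron_start <- exons[j - 1L, "end"]
    B <- intron_start
  }

  D <- if (s_idx > 1L) exons[s_idx - 1L, "end"] else NA_integer_
  E <- if (s_idx < n) exons[s_idx + 1L, "start"] else NA_integer_

  is_cryptic <- identical(v$class, "cryptic")
  J <- diff_lo <- diff_hi <- NA_integer_
  diff_mode <- NA_character_
  if (is_cryptic) {
    J <- v$cryptic_pos - 1L
    diff_lo <- min(A, J)
    diff_hi <- max(A, J)
    diff_mode <- if (J > intron_start && J < intron_end) {
      "spliced_in"   # cryptic isoform retains (A, J): exon extension
    } else {
      "spliced_out"  # cryptic isoform excises (J, A): exon truncation
    }
  }

  coords <- c(A, B, D, E, J)
  window_start <- max(0L, min(coords, na.rm = TRUE) - as.integer(max_read_len))
  window_end <- max(coords, na.rm = TRUE) + as.integer(max_read_len)

  tibble::tibble(
    variant_id = v$variant_id %||% NA_character_,
    transcript_id = tx$transcript_id,
    gene_symbol = tx$gene_symbol,
    chromosome = tx$chromosome,
    strand = v$strand,
    direction = dir,
    generalized = generalized,
    A = as.integer(A), B = as.integer(B),
    D = as.integer(D), E = as.integer(E), J = as.integer(J),
    intron_start = as.integer(intron_start),
    intron_end = as.integer(intron_end),
    diff_lo = as.integer(diff_lo), diff_hi = as.integer(diff_hi),
    diff_mode = diff_mode,
    window_start = as.integer(window_start),
    window_end = as.integer(window_end),
    variant_pos0 = as.integer(pos0),
    alt_allele = v$alt,
    is_cryptic = is_cryptic
  )
}

#' Resolve splice contexts for a variant across all isoforms of its gene
#'
#' Iterates over every transcript model of the variant's gene and keeps one
#' context per isoform on which the variant's stated geometry is resolvable.
#'
#' @param variant One-row variant tibble.
#' @param transcripts Annotation tibble from [read_refgene()].
#' @param max_read_len Fetch-window padding, see [build_splice_context()].
#' @return A tibble of contexts (possibly zero rows) with an attribute
#'   `skipped`: a character vector of per-isoform skip reasons.
#' @export
splice_contexts <- function(variant, transcripts, max_read_len = 1000L) {
  v <- as.list(variant)
  cand <- transcripts |>
    dplyr::filter(
      .data$gene_symbol == v$gene,
      .data$chromosome == v$chrom
    )
  skipped <- character()
  ctxs <- purrr::map(seq_len(nrow(cand)), function(i) {
    ctx <- build_splice_context(
      c(v, list(variant_id = v$variant_id %||% NA_character_)),
      cand[i, ], max_read_len
    )
    if (nrow(ctx) == 0L) {
      skipped <<- c(skipped, sprintf(
        "%s on %s: %s",
        v$variant_id %||% paste0(v$chrom, ":", v$pos),
        cand$transcript_id[i], attr(ctx, "reason")
      ))
    }
    ctx
  })
  out <- dplyr::bind_rows(ctxs)
  attr(out, "skipped") <- skipped
  out
}
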