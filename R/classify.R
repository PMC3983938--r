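#' Reference-aligned blocks of a read from its CIGAR string
#'
#' Splits an alignment into the genomic intervals it covers: match/mismatch
#' and deletion operations extend the current block, each reference-skip
#' (`N`, an intron in spliced RNA-Seq alignments) closes one block and opens
#' the next, and clips/insertions consume no reference. This realizes the
#' split-read coordinates `(r_s1, r_e1), (r_s2, r_e2)` that the junction
#' predicates are written over.
#'
#' @param cigar Character vector of CIGAR strings.
#' @param start0 Integer vector of 0-based leftmost reference positions.
#' @return A list of two-column integer matrices (`start`, `end`; 0-based
#'   half-open), one per alignment, blocks in genomic order.
#' @examples
#' cigar_blocks("20M100N20M", 80L)[[1]]  # (80,100) and (200,220)
#' @export
cigar_blocks <- function(cigar, start0) {
  bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad)) {
    stop("invalid CIGAR operation in: ", cigar[which(bad)[1]])
  }
  rl <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigar, pos = as.integer(start0) + 1L, drop.D.ranges = FALSE
  )
  flat <- unlist(rl, use.names = FALSE)
  starts <- IRanges::start(flat) - 1L
  ends <- IRanges::end(flat)
  sizes <- S4Vectors::elementNROWS(rl)
  offsets <- c(0L, cumsum(sizes))
  lapply(seq_along(sizes), function(i) {
    idx <- (offsets[i] + 1L):offsets[i + 1L]
    cbind(start = starts[idx], end = ends[idx])
  })
}

#' Base called by a read at a reference position
#'
#' Walks the CIGAR to map the reference position to the query offset.
#' Returns `NA` when the read does not cover the position (including when it
#' is deleted or skipped in the alignment).
#'
#' @param cigar CIGAR string (scalar).
#' @param start0 0-based leftmost reference position.
#' @param seq Query sequence as a character scalar.
#' @param pos0 0-based reference position of interest.
#' @return Single base character, or `NA_character_`.
#' @export
read_base_at <- function(cigar, start0, seq, pos0) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  rpos <- as.integer(start0)
  qpos <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]
    len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      if (pos0 >= rpos && pos0 < rpos + len) {
        return(substr(seq, qpos + (pos0 - rpos) + 1L,
                      qpos + (pos0 - rpos) + 1L))
      }
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (op == "D" && pos0 >= rpos && pos0 < rpos + len) {
        return(NA_character_)
      }
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    }
    # H and P consume neither
  }
  NA_character_
}

# reflect half-open blocks about junction A (mirror transform used to
# normalize a left-direction context to the right-direction predicates)
reflect_blocks <- function(blocks, A) {
  m <- cbind(start = 2L * A - blocks[, "end"], end = 2L * A - blocks[, "start"])
  m[rev(seq_len(nrow(m))), , drop = FALSE]
}

#' Classify aligned reads against one splice context
#'
#' Assigns each read at most one splicing consequence, with the evidence
#' type that supports it:
#'
#' * `exon_skipping` / junction-spanning — a split read joining the skip
#'   junction endpoints `D` and `E` exactly;
#' * `cryptic` / junction-spanning — the variant is cryptic and a split read
#'   joins the cryptic junction `J` to the natural junction `B` across the
#'   intron (by default the exact split-point test; with
#'   `strict_cryptic_split = FALSE` only the split gap length must equal
#'   `B - J`);
#' * `cryptic` / read-abundance — a contiguous read inside the differential
#'   region when that region is retained by the cryptic isoform (exon
#'   extension);
#' * `anti_cryptic` — a contiguous read inside the differential region when
#'   the cryptic isoform would excise it (exon truncation): the read
#'   contradicts cryptic-site use;
#' * `intron_inclusion` / junction-spanning — a contiguous read spanning the
#'   natural junction `A`;
#' * `intron_inclusion` / read-abundance — a contiguous read lying wholly
#'   within the affected intron;
#' * `normal_splice` — a split read whose junction coincides exactly with
#'   the natural junction (`A` to `B`);
#' * `none` — anything else.
#'
#' When several predicates hold, the junction-defining consequences win:
#' exon skipping > cryptic > intron inclusion > anti-cryptic > normal splice.
#' Left-direction contexts are handled by reflecting all coordinates about
#' `A` and applying the right-direction predicates. Reads with more than two
#' blocks are evaluated on each adjacent block pair.
#'
#' @param reads A tibble with a `blocks` list-column (as from
#'   [cigar_blocks()]); optional columns `read_id` and `base_at_variant`.
#' @param context One-row context tibble from [build_splice_context()].
#' @param strict_cryptic_split Use the exact split-point test for
#'   junction-spanning cryptic reads (default); `FALSE` restores the
#'   gap-length-only test.
#' @return The input tibble plus `consequence`, `evidence` and
#'   `carries_mutation` columns.
#' @export
classify_reads <- function(reads, context, strict_cryptic_split = TRUE) {
  ctx <- as.list(context)
  if (is.na(ctx$direction)) {
    stop("classify_reads(): context direction is unresolved")
  }
  A <- ctx$A
  refl <- identical(ctx$direction, "left")
  tr <- function(x) if (refl) 2L * A - x else x
  # normalized (direction = right) coordinates; D/E swap under reflection
  nB <- tr(ctx$B)
  nD <- if (refl) tr(ctx$E) else ctx$D
  nE <- if (refl) tr(ctx$D) else ctx$E
  nJ <- tr(ctx$J)
  dlo <- if (is.na(ctx$diff_lo)) NA_integer_ else min(tr(ctx$diff_lo), tr(ctx$diff_hi))
  dhi <- if (is.na(ctx$diff_hi)) NA_integer_ else max(tr(ctx$diff_lo), tr(ctx$diff_hi))
  spliced_in <- identical(ctx$diff_mode, "spliced_in")
  cryptic <- isTRUE(ctx$is_cryptic)

  n <- nrow(reads)
  consequence <- character(n)
  evidence <- character(n)
  blocks <- reads$blocks
  base_col <- if ("base_at_variant" %in% names(reads)) {
    reads$base_at_variant
  } else {
    rep(NA_character_, n)
  }

  for (i in seq_len(n)) {
    b <- blocks[[i]]
    if (refl) b <- reflect_blocks(b, A)
    nb <- nrow(b)
    single <- nb == 1L
    s <- b[1, "start"]
    e <- b[nb, "end"]

    es <- cs_js <- norm <- FALSE
    if (nb >= 2L) {
      e1 <- b[-nb, "end"]
      s2 <- b[-1, "start"]
      if (!is.na(nD) && !is.na(nE)) es <- any(e1 == nD & s2 == nE)
      if (cryptic) {
        cs_js <- if (strict_cryptic_split) {
          any(e1 == nJ & s2 == nB)
        } else {
          any(s2 - e1 == nB - nJ)
        }
      }
      norm <- any(e1 == A & s2 == nB)
    }
    in_diff <- cryptic && single && s >= dlo && e <= dhi
    cs_ra <- in_diff && spliced_in
    anti <- in_diff && !spliced_in
    ii_js <- single && s < A && e > A
    ii_ra <- single && s >= A && e <= nB && !ii_js

    if (es) {
      consequence[i] <- "exon_skipping"; evidence[i] <- "junction_spanning"
    } else if (cs_js) {
      consequence[i] <- "cryptic"; evidence[i] <- "junction_spanning"
    } else if (cs_ra) {
      consequence[i] <- "cryptic"; evidence[i] <- "read_abundance"
    } else if (ii_js) {
      consequence[i] <- "intron_inclusion"; evidence[i] <- "junction_spanning"
    } else if (ii_ra) {
      consequence[i] <- "intron_inclusion"; evidence[i] <- "read_abundance"
    } else if (anti) {
      consequence[i] <- "anti_cryptic"; evidence[i] <- "not_applicable"
    } else if (norm) {
      consequence[i] <- "normal_splice"; evidence[i] <- "not_applicable"
    } else {
      consequence[i] <- "none"; evidence[i] <- "not_applicable"
    }
  }

  reads |>
    dplyr::mutate(
      consequence = consequence,
      evidence = evidence,
      carries_mutation = !is.na(base_col) & base_col == ctx$alt_allele
    )
}

category_levels <- function() {
  c("cs_js", "cs_ra", "anti_cryptic", "es_js", "ii_js", "ii_jswm", "ii_ra",
    "ii_total", "normal_splice")
}

classification_category <- function(consequence, evidence) {
  dplyr::case_when(
    consequence == "cryptic" & evidence == "junction_spanning" ~ "cs_js",
    consequence == "cryptic" & evidence == "read_abundance" ~ "cs_ra",
    consequence == "exon_skipping" ~ "es_js",
    consequence == "intron_inclusion" & evidence == "junction_spanning" ~ "ii_js",
    consequence == "intron_inclusion" & evidence == "read_abundance" ~ "ii_ra",
    consequence == "anti_cryptic" ~ "anti_cryptic",
    consequence == "normal_splice" ~ "normal_splice",
    TRUE ~ "none"
  )
}

#' Tally validated reads for one sample across all isoform contexts
#'
#' Classifies every read under each context and counts each read at most
#' once per evidence category, whichever isoform supports the call. The
#' returned row carries the per-category counts used as the \eqn{V_j} of the
#' downstream statistics, plus `ii_total = ii_js + ii_ra`, the
#' mutation-carrying subset of junction-spanning intron inclusion
#' (`ii_jswm`), and the cryptic read fraction (cryptic-supporting over
#' anti-cryptic reads; `NA` when no anti-cryptic reads were seen).
#'
#' @param reads Read tibble for one sample (see [classify_reads()]); may
#'   have zero rows.
#' @param contexts Context tibble (one row per isoform) for one variant.
#' @param sample_id Sample label for the output row.
#' @param strict_cryptic_split Passed to [classify_reads()].
#' @return A one-row tibble of counts.
#' @export
count_region <- function(reads, contexts, sample_id = NA_character_,
                         strict_cryptic_split = TRUE) {
  zero <- tibble::tibble(
    sample_id = sample_id,
    cs_js = 0L, cs_ra = 0L, anti_cryptic = 0L, es_js = 0L,
    ii_js = 0L, ii_jswm = 0L, ii_ra = 0L, ii_total = 0L,
    normal_splice = 0L, none = 0L, total_reads = 0L,
    read_fraction = NA_real_
  )
  if (nrow(reads) == 0L || nrow(contexts) == 0L) {
    zero$none <- nrow(reads)
    zero$total_reads <- nrow(reads)
    return(zero)
  }
  per_ctx <- purrr::map(seq_len(nrow(contexts)), function(k) {
    cl <- classify_reads(reads, contexts[k, ], strict_cryptic_split)
    classification_category(cl$consequence, cl$evidence)
  })
  carries <- classify_reads(reads, contexts[1, ],
                            strict_cryptic_split)$carries_mutation
  cat_mat <- do.call(cbind, per_ctx)  # reads x contexts
  count_cat <- function(cat) sum(apply(cat_mat == cat, 1L, any))
  cs_js <- count_cat("cs_js")
  cs_ra <- count_cat("cs_ra")
  anti <- count_cat("anti_cryptic")
  es_js <- count_cat("es_js")
  ii_js_hit <- apply(cat_mat == "ii_js", 1L, any)
  ii_js <- sum(ii_js_hit)
  ii_jswm <- sum(ii_js_hit & carries)
  ii_ra <- count_cat("ii_ra")
  normal <- count_cat("normal_splice")
  none <- sum(apply(cat_mat == "none", 1L, all))
  tibble::tibble(
    sample_id = sample_id,
    cs_js = cs_js, cs_ra = cs_ra, anti_cryptic = anti, es_js = es_js,
    ii_js = ii_js, ii_jswm = ii_jswm, ii_ra = ii_ra,
    ii_total = ii_js + ii_ra,
    normal_splice = normal, none = none, total_reads = nrow(reads),
    read_fraction = if (anti > 0) (cs_js + cs_ra) / anti else NA_real_
  )
}

#' Fetch filtered reads from an indexed BAM file over a genomic window
#'
#' Retrieves primary, mapped, non-duplicate, QC-passing alignments
#' overlapping the window, applies the mapping-quality floor, derives the
#' aligned block structure from the CIGARs, and (for reads covering the
#' variant position) records the called base there. Contig naming is
#' normalized: if the requested chromosome is absent from the BAM header the
#' `chr` prefix is added or stripped as needed.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param chromosome Chromosome name (annotation convention).
#' @param window_start,window_end 0-based half-open fetch window.
#' @param variant_pos0 0-based variant position for base extraction, or
#'   `NA` to skip it.
#' @param min_mapq Minimum mapping quality (default 1); records with
#'   missing mapping quality (255) are kept.
#' @return A read tibble with `read_id`, `blocks`, `length`, `mapq`,
#'   `base_at_variant`.
#' @export
.bam_target_cache <- new.env(parent = emptyenv())

bam_targets <- function(bam) {
  key <- paste0(bam, "#", file.mtime(bam))
  hit <- .bam_target_cache[[key]]
  if (!is.null(hit)) return(hit)
  targets <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
  assign(key, targets, envir = .bam_target_cache)
  targets
}

fetch_reads <- function(bam, chromosome, window_start, window_end,
                        variant_pos0 = NA_integer_, min_mapq = 1L) {
  targets <- bam_targets(bam)
  chrom <- chromosome
  if (!chrom %in% targets) {
    alt <- if (startsWith(chrom, "chr")) sub("^chr", "", chrom) else paste0("chr", chrom)
    if (alt %in% targets) chrom <- alt
  }
  empty <- tibble::tibble(
    read_id = character(), blocks = list(), length = integer(),
    mapq = integer(), base_at_variant = character()
  )
  if (!chrom %in% targets) return(empty)
  param_key <- paste(chrom, window_start, window_end, sep = "\r")
  param <- .bam_target_cache[[param_key]]
  if (is.null(param)) {
    which <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(window_start + 1L, window_end)
    )
    param <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(
        isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
        isDuplicate = FALSE, isNotPassingQualityControls = FALSE,
        isSupplementaryAlignment = FALSE
      ),
      what = c("qname", "pos", "mapq", "cigar", "seq"),
      which = which
    )
    assign(param_key, param, envir = .bam_target_cache)
  }
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(res$qname) == 0L) return(empty)
  mapq <- res$mapq
  keep <- is.na(mapq) | mapq >= min_mapq
  if (!any(keep)) return(empty)
  qname <- res$qname[keep]
  pos0 <- res$pos[keep] - 1L
  cigar <- res$cigar[keep]
  seqs <- as.character(res$seq[keep])
  blocks <- cigar_blocks(cigar, pos0)
  base <- rep(NA_character_, length(qname))
  if (!is.na(variant_pos0)) {
    covers <- vapply(
      blocks,
      function(b) any(b[, "start"] <= variant_pos0 & variant_pos0 < b[, "end"]),
      logical(1)
    )
    for (i in which(covers)) {
      base[i] <- read_base_at(cigar[i], pos0[i], seqs[i], variant_pos0)
    }
  }
  tibble::tibble(
    read_id = qname,
    blocks = blocks,
    length = vapply(blocks, function(b) sum(b[, "end"] - b[, "start"]), integer(1)),
    mapq = as.integer(res$mapq[keep]),
    base_at_variant = base
  )
}
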