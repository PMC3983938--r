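sim_categories <- function() {
  c("cs_js", "cs_ra", "es_js", "ii_js", "ii_ra", "anti_cryptic",
    "normal_splice")
}

#' Define a synthetic splicing-aberration scenario
#'
#' A scenario bundles a synthetic gene model, one predicted splice variant
#' on it, the read counts to plant in carrier samples, and the control-count
#' model. It emulates the structure of a real cohort input — annotation,
#' variant table, aligned reads per sample — with none of the sequence-level
#' realism (constant qualities, flat base composition): classification
#' depends only on alignment block structure and the base at the variant
#' position.
#'
#' The variant is placed at the affected natural junction: the last/first
#' exonic base for exonic variants, the first/last intronic base for
#' intronic ones. For cryptic variants the cryptic junction sits
#' `jc_offset` bp from the natural junction, inside the intron
#' (`cryptic_side = "intron"`: exon extension, differential region
#' spliced-in) or inside the exon (`"exon"`: truncation, spliced-out).
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param n_exons,exon_len,intron_len Gene geometry in bp.
#' @param gene_offset Genomic offset of the first exon (use distinct
#'   offsets to place several scenarios on one chromosome).
#' @param variant_exon Index of the exon whose splice site is affected
#'   (must have an intron on the checking side).
#' @param site_kind,region,variant_class Variant geometry, see
#'   [read_splice_variants()].
#' @param cryptic_side `"intron"` or `"exon"` (cryptic variants only).
#' @param jc_offset Distance from the natural junction to the cryptic
#'   junction, bp.
#' @param ref,alt Variant alleles.
#' @param initial_ri,final_ri Individual-information fields copied into the
#'   variant table (bits).
#' @param read_len Simulated read length, bp.
#' @param n_experimental,n_normals Cohort sizes.
#' @param carriers Integer indices of the experimental samples carrying the
#'   variant.
#' @param planted Named numeric vector of read counts planted in each
#'   carrier: any of `cs_js`, `cs_ra`, `es_js`, `ii_js`, `ii_ra`,
#'   `anti_cryptic`, `normal_splice`.
#' @param mutant_fraction Fraction of planted junction-spanning
#'   intron-inclusion reads that carry the alternate base.
#' @param control_means Named numeric vector of Poisson means for the
#'   per-category counts of non-carrier samples.
#' @return A `splice_scenario` list with the resolved gene model
#'   (`transcripts` tibble), `variant` row, and all parameters.
#' @export
splice_scenario <- function(gene = "GENE1", chrom = "chrS", strand = "+",
                            n_exons = 3L, exon_len = 150L, intron_len = 300L,
                            gene_offset = 0L, variant_exon = 2L,
                            site_kind = "donor", region = "exonic",
                            variant_class = "natural",
                            cryptic_side = c("intron", "exon"),
                            jc_offset = 100L,
                            ref = "G", alt = "T",
                            initial_ri = 9.8, final_ri = 7.6,
                            read_len = 50L,
                            n_experimental = 10L, n_normals = 4L,
                            carriers = 1L,
                            planted = c(normal_splice = 20),
                            mutant_fraction = 0,
                            control_means = c(normal_splice = 20,
                                              ii_ra = 4)) {
  cryptic_side <- match.arg(cryptic_side)
  stopifnot(
    n_exons >= 2L, variant_exon >= 1L, variant_exon <= n_exons,
    exon_len > read_len, intron_len > read_len,
    all(names(planted) %in% sim_categories()),
    all(names(control_means) %in% sim_categories()),
    all(planted >= 0), all(control_means >= 0),
    mutant_fraction >= 0, mutant_fraction <= 1
  )
  starts <- gene_offset + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  exons <- cbind(start = as.integer(starts),
                 end = as.integer(starts + exon_len))
  transcripts <- tibble::tibble(
    gene_symbol = gene,
    transcript_id = paste0("TX_", gene, "_1"),
    chromosome = chrom,
    strand = strand,
    tx_start = exons[1, "start"],
    tx_end = exons[n_exons, "end"],
    n_exons = n_exons,
    exons = list(exons)
  )

  ve <- variant_exon
  # natural junction of the stated site kind on the variant exon
  A <- if (site_kind == "donor") {
    if (strand == "+") exons[ve, "end"] else exons[ve, "start"]
  } else {
    if (strand == "+") exons[ve, "start"] else exons[ve, "end"]
  }
  dir <- as.character(resolve_direction(region, site_kind, strand))
  if ((dir == "right" && !any(exons[, "end"] == A & seq_len(n_exons) < n_exons)) ||
      (dir == "left" && !any(exons[, "start"] == A & seq_len(n_exons) > 1L))) {
    stop("splice_scenario(): variant_exon has no intron on the checking side")
  }
  pos0 <- if (region == "exonic") {
    if (dir == "right") A - 1L else A
  } else {
    if (dir == "right") A else A - 1L
  }
  cryptic_pos <- NA_integer_
  if (variant_class == "cryptic") {
    into_intron <- cryptic_side == "intron"
    stopifnot(jc_offset > 0L,
              jc_offset < (if (into_intron) intron_len else exon_len))
    J <- if (dir == "right") {
      if (into_intron) A + jc_offset else A - jc_offset
    } else {
      if (into_intron) A - jc_offset else A + jc_offset
    }
    cryptic_pos <- as.integer(J) + 1L
  }

  carriers <- as.integer(carriers)
  stopifnot(all(carriers >= 1L), all(carriers <= n_experimental))
  sample_ids <- sprintf("TUMOR%03d", seq_len(n_experimental))
  variant <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos0) + 1L, ref = ref, alt = alt,
    gene = gene, strand = strand, site_kind = site_kind, region = region,
    class = variant_class,
    initial_ri = initial_ri, final_ri = final_ri,
    cryptic_pos = cryptic_pos,
    samples = paste(sample_ids[carriers], collapse = ","),
    delta_ri = final_ri - initial_ri,
    sample_ids = list(sample_ids[carriers]),
    variant_id = sprintf("%s:%d%s>%s", chrom, as.integer(pos0) + 1L, ref, alt)
  )

  structure(
    list(
      gene = gene, chrom = chrom, strand = strand,
      transcripts = transcripts, variant = variant,
      read_len = as.integer(read_len),
      n_experimental = as.integer(n_experimental),
      n_normals = as.integer(n_normals),
      carriers = carriers,
      planted = planted, mutant_fraction = mutant_fraction,
      control_means = control_means
    ),
    class = "splice_scenario"
  )
}

scenario_context <- function(scenario) {
  ctx <- build_splice_context(scenario$variant, scenario$transcripts[1, ])
  if (nrow(ctx) == 0L) {
    stop("splice_scenario is internally inconsistent: ", attr(ctx, "reason"))
  }
  ctx
}

#' Simulate aligned reads realizing given evidence-category counts
#'
#' Emits one alignment record per planted read; the block geometry of each
#' record is constructed so that the read classifies into exactly its
#' intended category under the scenario's splice context (split reads
#' joining the skip junction for exon skipping, the cryptic-to-natural
#' junction for cryptic use, contiguous reads over or inside the intron for
#' inclusion, exact natural splits for normal splicing). Start offsets
#' within the permitted range are drawn from the current RNG.
#'
#' @param scenario A `splice_scenario`.
#' @param counts Named numeric vector of per-category read counts (see
#'   [splice_scenario()]'s `planted`).
#' @param mutant_fraction Fraction of junction-spanning intron-inclusion
#'   reads carrying the alternate base at the variant position.
#' @param prefix Read-name prefix.
#' @return A tibble of alignment records: `qname`, `pos0`, `cigar`, `seq`,
#'   plus the intended `category`.
#' @export
simulate_reads <- function(scenario, counts = scenario$planted,
                           mutant_fraction = scenario$mutant_fraction,
                           prefix = "r") {
  ctx <- scenario_context(scenario)
  L <- scenario$read_len
  A <- ctx$A
  B <- ctx$B
  ilo <- ctx$intron_start
  ihi <- ctx$intron_end
  intron_len <- ihi - ilo
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    return(tibble::tibble(qname = character(), pos0 = integer(),
                          cigar = character(), seq = character(),
                          category = character()))
  }

  split_read <- function(left_end, right_start) {
    k <- sample(seq_len(L - 1L), 1L)
    list(blocks = cbind(start = c(left_end - k, right_start),
                        end = c(left_end, right_start + (L - k))))
  }
  make_one <- function(category) {
    switch(category,
      es_js = {
        if (is.na(ctx$D) || is.na(ctx$E)) {
          stop("cannot plant exon-skipping reads: no flanking exon on one side")
        }
        split_read(ctx$D, ctx$E)
      },
      cs_js = {
        if (!ctx$is_cryptic) stop("cannot plant cryptic reads for a non-cryptic variant")
        split_read(min(ctx$J, B), max(ctx$J, B))
      },
      normal_splice = split_read(min(A, B), max(A, B)),
      ii_js = {
        k <- sample(seq_len(L - 1L), 1L)
        list(blocks = cbind(start = A - k, end = A - k + L))
      },
      ii_ra = {
        lo <- ilo
        hi <- ihi
        if (ctx$is_cryptic && identical(ctx$diff_mode, "spliced_in")) {
          # keep intronic filler reads out of the differential region
          if (ctx$diff_lo == ilo) lo <- ctx$diff_hi else hi <- ctx$diff_lo
        }
        if (hi - lo < L) stop("intron segment shorter than the read length")
        s <- lo + sample.int(hi - lo - L + 1L, 1L) - 1L
        list(blocks = cbind(start = s, end = s + L))
      },
      cs_ra = {
        if (!identical(ctx$diff_mode, "spliced_in")) {
          stop("cryptic read-abundance reads require a spliced-in differential region")
        }
        span <- ctx$diff_hi - ctx$diff_lo
        if (span < L) stop("differential region shorter than the read length")
        s <- ctx$diff_lo + sample.int(span - L + 1L, 1L) - 1L
        list(blocks = cbind(start = s, end = s + L))
      },
      anti_cryptic = {
        if (!identical(ctx$diff_mode, "spliced_out")) {
          stop("anti-cryptic reads require a spliced-out differential region")
        }
        span <- ctx$diff_hi - ctx$diff_lo
        if (span < L) stop("differential region shorter than the read length")
        s <- ctx$diff_lo + sample.int(span - L + 1L, 1L) - 1L
        list(blocks = cbind(start = s, end = s + L))
      },
      stop("unknown planted category: ", category)
    )
  }

  rows <- list()
  idx <- 0L
  for (cat in names(counts)) {
    n_cat <- as.integer(counts[[cat]])
    n_mut <- if (cat == "ii_js") round(mutant_fraction * n_cat) else 0L
    for (j in seq_len(n_cat)) {
      idx <- idx + 1L
      r <- make_one(cat)
      b <- r$blocks
      rows[[idx]] <- tibble::tibble(
        qname = sprintf("%s%05d_%s", prefix, idx, cat),
        pos0 = b[1, "start"],
        cigar = blocks_to_cigar(b),
        seq = read_sequence(b, ctx$variant_pos0,
                            if (j <= n_mut) scenario$variant$alt
                            else scenario$variant$ref),
        category = cat
      )
    }
  }
  dplyr::bind_rows(rows)
}

blocks_to_cigar <- function(blocks) {
  n <- nrow(blocks)
  parts <- character(2L * n - 1L)
  parts[seq(1L, 2L * n - 1L, by = 2L)] <-
    paste0(blocks[, "end"] - blocks[, "start"], "M")
  if (n > 1L) {
    gaps <- blocks[-1L, "start"] - blocks[-n, "end"]
    parts[seq(2L, 2L * n - 2L, by = 2L)] <- paste0(gaps, "N")
  }
  paste(parts, collapse = "")
}

read_sequence <- function(blocks, variant_pos0, variant_base) {
  len <- sum(blocks[, "end"] - blocks[, "start"])
  bases <- rep("A", len)
  q <- 0L
  for (i in seq_len(nrow(blocks))) {
    s <- blocks[i, "start"]
    e <- blocks[i, "end"]
    if (!is.na(variant_pos0) && variant_pos0 >= s && variant_pos0 < e) {
      bases[q + (variant_pos0 - s) + 1L] <- variant_base
    }
    q <- q + (e - s)
  }
  paste(bases, collapse = "")
}

write_sample_bam <- function(records, chrom, chrom_len, bam_path) {
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len)
  )
  body <- if (nrow(records) > 0) {
    qual <- vapply(records$seq, function(s) strrep("I", nchar(s)), character(1))
    sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
            records$qname, chrom, records$pos0 + 1L, records$cigar,
            records$seq, qual)
  } else {
    character()
  }
  readr::write_lines(c(header, body), sam)
  dest <- sub("\\.bam$", "", bam_path)
  Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
  bam_path
}

#' Build a self-contained synthetic validation cohort on disk
#'
#' Writes everything the pipeline needs: a refGene annotation covering all
#' scenarios, a variant table, one coordinate-sorted indexed BAM per sample
#' (carriers receive their scenario's planted reads; every other sample
#' draws per-category counts from the scenario's Poisson control model),
#' and the two BAM list files. All scenarios must share the cohort shape
#' (`n_experimental`, `n_normals`) of the first one and use distinct
#' genomic intervals (`gene_offset`).
#'
#' The control model samples category counts independently per sample; it
#' makes no attempt to model batch effects or expression-level structure,
#' matching the method's reliance on a large cohort to even those out.
#'
#' @param scenarios A `splice_scenario` or list of them.
#' @param dir Output directory.
#' @param seed Integer seed; the tree is a deterministic function of
#'   (scenarios, seed).
#' @return A list of paths: `annotation`, `variants`,
#'   `experimental_list`, `normal_list`, `dir`, plus the sample tables.
#' @export
build_cohort <- function(scenarios, dir, seed = 1L) {
  if (inherits(scenarios, "splice_scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) > 0)
  first <- scenarios[[1]]
  same <- vapply(scenarios, function(s) {
    s$n_experimental == first$n_experimental &&
      s$n_normals == first$n_normals
  }, logical(1))
  stopifnot(all(same))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bam_dir <- file.path(dir, "bam")
  dir.create(bam_dir, showWarnings = FALSE)
  set.seed(as.integer(seed))

  annotation <- dplyr::bind_rows(purrr::map(scenarios, "transcripts"))
  ann_path <- file.path(dir, "annotation.refgene.txt")
  write_refgene(annotation, ann_path)
  variants <- dplyr::bind_rows(purrr::map(scenarios, function(s) s$variant))
  var_path <- file.path(dir, "variants.tsv")
  write_splice_variants(variants, var_path)

  chrom <- first$chrom
  stopifnot(all(vapply(scenarios, function(s) s$chrom == chrom, logical(1))))
  chrom_len <- max(annotation$tx_end) + 10000L

  exp_ids <- sprintf("TUMOR%03d", seq_len(first$n_experimental))
  norm_ids <- sprintf("NORMAL%03d", seq_len(first$n_normals))

  draw_control_counts <- function(s) {
    means <- s$control_means
    counts <- stats::rpois(length(means), means)
    names(counts) <- names(means)
    counts
  }

  sample_records <- function(sample_id, is_experimental, exp_index) {
    recs <- purrr::imap(scenarios, function(s, si) {
      is_carrier <- is_experimental && exp_index %in% s$carriers
      if (is_carrier) {
        simulate_reads(s, prefix = sprintf("%s_g%d_", sample_id, si))
      } else {
        simulate_reads(s, counts = draw_control_counts(s),
                       mutant_fraction = 0,
                       prefix = sprintf("%s_g%d_", sample_id, si))
      }
    })
    dplyr::bind_rows(recs)
  }

  exp_paths <- file.path(bam_dir, paste0(exp_ids, ".bam"))
  for (i in seq_along(exp_ids)) {
    write_sample_bam(sample_records(exp_ids[i], TRUE, i), chrom, chrom_len,
                     exp_paths[i])
  }
  norm_paths <- file.path(bam_dir, paste0(norm_ids, ".bam"))
  for (i in seq_along(norm_ids)) {
    write_sample_bam(sample_records(norm_ids[i], FALSE, NA_integer_), chrom,
                     chrom_len, norm_paths[i])
  }

  exp_list <- file.path(dir, "experimental_bams.txt")
  norm_list <- file.path(dir, "normal_bams.txt")
  readr::write_lines(file.path("bam", basename(exp_paths)), exp_list)
  readr::write_lines(file.path("bam", basename(norm_paths)), norm_list)

  list(
    dir = dir,
    annotation = ann_path,
    variants = var_path,
    experimental_list = exp_list,
    normal_list = norm_list,
    experimental = tibble::tibble(sample_id = exp_ids, path = exp_paths),
    normals = tibble::tibble(sample_id = norm_ids, path = norm_paths)
  )
}
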