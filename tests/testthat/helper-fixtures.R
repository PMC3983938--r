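# Shared fixtures: the canonical classifier test context, an independent
# brute-force transcription of the read partitions, and random read
# generators. The oracle deliberately evaluates every predicate from the
# printed set definitions (no shared code with classify_reads()).

# canonical context: direction right, A = 100, B = 200, D = 100, E = 400,
# intron (100, 200), cryptic junction J = 150, differential region
# (100, 150) spliced in. Variant base at position 99 (alt "T").
canonical_context <- function(cryptic = TRUE) {
  tibble::tibble(
    variant_id = "test:100G>T",
    transcript_id = "TX1", gene_symbol = "G1", chromosome = "chrT",
    strand = "+", direction = "right", generalized = FALSE,
    A = 100L, B = 200L, D = 100L, E = 400L,
    J = if (cryptic) 150L else NA_integer_,
    intron_start = 100L, intron_end = 200L,
    diff_lo = if (cryptic) 100L else NA_integer_,
    diff_hi = if (cryptic) 150L else NA_integer_,
    diff_mode = if (cryptic) "spliced_in" else NA_character_,
    window_start = 0L, window_end = 1400L,
    variant_pos0 = 99L, alt_allele = "T",
    is_cryptic = cryptic
  )
}

read_tbl <- function(...) {
  blocks <- list(...)
  tibble::tibble(
    read_id = sprintf("r%02d", seq_along(blocks)),
    blocks = lapply(blocks, function(b) {
      m <- matrix(as.integer(t(b)), ncol = 2, byrow = TRUE)
      colnames(m) <- c("start", "end")
      m
    })
  )
}

# literal set-definition transcription, one read at a time
oracle_classify_one <- function(blocks, ctx, strict_cryptic_split = TRUE) {
  A <- ctx$A
  if (identical(ctx$direction, "left")) {
    blocks <- cbind(start = 2L * A - blocks[, "end"],
                    end = 2L * A - blocks[, "start"])
    blocks <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
    B <- 2L * A - ctx$B
    D <- if (is.na(ctx$E)) NA_integer_ else 2L * A - ctx$E
    E <- if (is.na(ctx$D)) NA_integer_ else 2L * A - ctx$D
    J <- if (is.na(ctx$J)) NA_integer_ else 2L * A - ctx$J
    dlo <- if (is.na(ctx$diff_lo)) NA else min(2L * A - ctx$diff_lo, 2L * A - ctx$diff_hi)
    dhi <- if (is.na(ctx$diff_hi)) NA else max(2L * A - ctx$diff_lo, 2L * A - ctx$diff_hi)
  } else {
    B <- ctx$B; D <- ctx$D; E <- ctx$E; J <- ctx$J
    dlo <- ctx$diff_lo; dhi <- ctx$diff_hi
  }
  cryptic <- isTRUE(ctx$is_cryptic)
  spliced_in <- identical(ctx$diff_mode, "spliced_in")
  nb <- nrow(blocks)
  single <- nb == 1L
  rs <- blocks[1, "start"]
  re <- blocks[nb, "end"]
  pairs <- if (nb >= 2L) {
    cbind(re1 = blocks[-nb, "end"], rs2 = blocks[-1, "start"])
  } else {
    matrix(integer(), ncol = 2, dimnames = list(NULL, c("re1", "rs2")))
  }
  spans_A <- single && rs < A && re > A

  split_cryptic <- cryptic && nrow(pairs) > 0 && !is.na(J) &&
    (if (strict_cryptic_split) any(pairs[, "re1"] == J & pairs[, "rs2"] == B)
     else any(pairs[, "rs2"] - pairs[, "re1"] == B - J))
  in_region <- cryptic && single && !is.na(dlo) && rs >= dlo && re <= dhi
  zeta_c <- split_cryptic || (in_region && spliced_in)
  anti <- in_region && !spliced_in
  zeta_e <- nrow(pairs) > 0 && !is.na(D) && !is.na(E) &&
    any(pairs[, "re1"] == D & pairs[, "rs2"] == E)
  zeta_i <- spans_A ||
    (single && !spans_A && rs >= A && re <= B)
  normal <- nrow(pairs) > 0 && any(pairs[, "re1"] == A & pairs[, "rs2"] == B)
  delta <- spans_A || split_cryptic

  if (zeta_e) {
    c("exon_skipping", "junction_spanning")
  } else if (zeta_c) {
    c("cryptic", if (delta) "junction_spanning" else "read_abundance")
  } else if (zeta_i) {
    c("intron_inclusion", if (delta) "junction_spanning" else "read_abundance")
  } else if (anti) {
    c("anti_cryptic", "not_applicable")
  } else if (normal) {
    c("normal_splice", "not_applicable")
  } else {
    c("none", "not_applicable")
  }
}

oracle_classify <- function(reads, ctx, strict_cryptic_split = TRUE) {
  res <- t(vapply(reads$blocks, oracle_classify_one, character(2),
                  ctx = as.list(ctx),
                  strict_cryptic_split = strict_cryptic_split))
  tibble::tibble(consequence = res[, 1], evidence = res[, 2])
}

# random reads around a context: a mix of single-block and split reads whose
# endpoints are biased toward the context's landmark coordinates so that
# every predicate branch is exercised
random_reads <- function(ctx, n) {
  landmarks <- stats::na.omit(c(ctx$A, ctx$B, ctx$D, ctx$E, ctx$J))
  lo <- min(landmarks) - 150L
  hi <- max(landmarks) + 150L
  pick_point <- function(m) {
    special <- stats::runif(m) < 0.5
    out <- integer(m)
    out[special] <- sample(landmarks, sum(special), replace = TRUE)
    out[!special] <- sample(seq(lo, hi), sum(!special), replace = TRUE)
    out
  }
  blocks <- vector("list", n)
  is_split <- stats::runif(n) < 0.5
  for (i in seq_len(n)) {
    len <- sample(20:80, 1)
    if (is_split[i]) {
      e1 <- pick_point(1L)
      s2 <- e1 + sample(c(ctx$B - ctx$A,
                          if (!is.na(ctx$J)) abs(ctx$B - ctx$J),
                          sample(30:500, 2)), 1)
      k <- sample(seq_len(len - 1L), 1)
      blocks[[i]] <- cbind(start = c(e1 - k, s2), end = c(e1, s2 + (len - k)))
    } else {
      s <- pick_point(1L) - sample(0:len, 1)
      blocks[[i]] <- cbind(start = s, end = s + len)
    }
  }
  tibble::tibble(read_id = sprintf("rr%05d", seq_len(n)), blocks = blocks)
}

# the four direction/strand geometries used by oracle and mirror tests
geometry_scenarios <- function() {
  list(
    exonic_donor_plus = splice_scenario(
      gene = "GP", strand = "+", site_kind = "donor", region = "exonic",
      variant_class = "cryptic", cryptic_side = "intron"
    ),
    exonic_donor_minus = splice_scenario(
      gene = "GM", strand = "-", site_kind = "donor", region = "exonic",
      variant_class = "cryptic", cryptic_side = "exon"
    ),
    intronic_acceptor_plus = splice_scenario(
      gene = "AP", strand = "+", site_kind = "acceptor", region = "intronic",
      variant_class = "cryptic", cryptic_side = "intron"
    ),
    intronic_acceptor_minus = splice_scenario(
      gene = "AM", strand = "-", site_kind = "acceptor", region = "intronic",
      variant_class = "cryptic", cryptic_side = "exon"
    )
  )
}

scenario_ctx <- function(sc) {
  build_splice_context(sc$variant, sc$transcripts[1, ])
}
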