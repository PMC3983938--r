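make_variant <- function(pos, site_kind = "donor", region = "exonic",
                         class = "natural", cryptic_pos = NA_integer_,
                         strand = "+", gene = "GENE1", chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = "G", alt = "T",
    gene = gene, strand = strand, site_kind = site_kind, region = region,
    class = class, initial_ri = 10, final_ri = 8,
    cryptic_pos = as.integer(cryptic_pos),
    samples = "S1", delta_ri = -2, sample_ids = list("S1"),
    variant_id = sprintf("%s:%d%s>%s", chrom, as.integer(pos), "G", "T")
  )
}

three_exon_tx <- function(strand = "+") {
  tibble::tibble(
    gene_symbol = "GENE1", transcript_id = "NM_0001", chromosome = "chr1",
    strand = strand, tx_start = 0L, tx_end = 500L, n_exons = 3L,
    exons = list(cbind(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L)))
  )
}

test_that("checking direction reproduces all four published rows", {
  expect_equal(as.character(resolve_direction("exonic", "donor", "+")), "right")
  expect_equal(as.character(resolve_direction("exonic", "donor", "-")), "left")
  expect_equal(as.character(resolve_direction("intronic", "acceptor", "+")), "left")
  expect_equal(as.character(resolve_direction("intronic", "acceptor", "-")), "right")
  expect_false(any(attr(resolve_direction(
    c("exonic", "intronic"), c("donor", "acceptor"), c("+", "-")
  ), "generalized")))
})

test_that("uncovered direction pairs generalize by default and error in strict mode", {
  d <- resolve_direction("exonic", "acceptor", "+")
  expect_equal(as.character(d), "left")
  expect_true(attr(d, "generalized"))
  d2 <- resolve_direction("intronic", "donor", "-")
  expect_equal(as.character(d2), "left")
  expect_error(
    resolve_direction("exonic", "acceptor", "+", generalize = FALSE),
    "direction undefined"
  )
})

test_that("a donor variant at the first exon boundary resolves A and B", {
  # exons [0,100), [200,300), [400,500); donor at the end of exon 1
  ctx <- build_splice_context(make_variant(100), three_exon_tx())
  expect_equal(ctx$direction, "right")
  expect_equal(ctx$A, 100L)
  expect_equal(ctx$B, 200L)
  expect_equal(ctx$intron_start, 100L)
  expect_equal(ctx$intron_end, 200L)
  # first exon: no upstream flanking exon, so the skip junction is disabled
  expect_true(is.na(ctx$D))
  expect_equal(ctx$E, 200L)
  expect_equal(ctx$B, ctx$E)
})

test_that("a middle-exon variant yields skip endpoints flanking its exon", {
  # donor at the end of exon 2: skip junction joins exon 1 end to exon 3 start
  ctx <- build_splice_context(make_variant(300), three_exon_tx())
  expect_equal(ctx$A, 300L)
  expect_equal(ctx$B, 400L)
  expect_equal(ctx$D, 100L)
  expect_equal(ctx$E, 400L)
  expect_true(ctx$D < ctx$A && ctx$A < ctx$E)
  # acceptor-side intronic variant on the same exon: direction left, B = D
  ctx2 <- build_splice_context(
    make_variant(150, site_kind = "acceptor", region = "intronic"),
    three_exon_tx()
  )
  expect_equal(ctx2$direction, "left")
  expect_equal(ctx2$A, 200L)
  expect_equal(ctx2$B, 100L)
  expect_equal(ctx2$D, 100L)
  expect_equal(ctx2$B, ctx2$D)
  expect_equal(ctx2$E, 400L)
})

test_that("a cryptic junction inside the downstream intron is spliced in", {
  v <- make_variant(300, class = "cryptic", cryptic_pos = 351L)
  ctx <- build_splice_context(v, three_exon_tx())
  expect_equal(ctx$J, 350L)
  expect_equal(ctx$diff_lo, 300L)
  expect_equal(ctx$diff_hi, 350L)
  expect_equal(ctx$diff_mode, "spliced_in")
  # cryptic junction on the exonic side: truncation, spliced out
  v2 <- make_variant(300, class = "cryptic", cryptic_pos = 261L)
  ctx2 <- build_splice_context(v2, three_exon_tx())
  expect_equal(ctx2$J, 260L)
  expect_equal(ctx2$diff_mode, "spliced_out")
})

test_that("every isoform of the gene yields its own context", {
  tx2 <- three_exon_tx()
  tx2$transcript_id <- "NM_0002"
  tx2$exons <- list(cbind(start = c(0L, 400L), end = c(100L, 500L)))
  tx2$n_exons <- 2L
  ann <- dplyr::bind_rows(three_exon_tx(), tx2)
  ctxs <- splice_contexts(make_variant(100), ann)
  expect_equal(nrow(ctxs), 2L)
  expect_equal(ctxs$B, c(200L, 400L))
})

test_that("variants outside a transcript's neighborhoods are skipped with a reason", {
  ctxs <- splice_contexts(make_variant(9000), three_exon_tx())
  expect_equal(nrow(ctxs), 0L)
  expect_match(attr(ctxs, "skipped"), "outside transcript span")
  # declared exonic but intronic on this isoform
  ctxs2 <- splice_contexts(make_variant(150), three_exon_tx())
  expect_match(attr(ctxs2, "skipped"), "falls in an intron")
  # donor of the last exon: no intron on the checking side
  ctxs3 <- splice_contexts(make_variant(500), three_exon_tx())
  expect_match(attr(ctxs3, "skipped"), "no intron on the checking side")
})

test_that("query window spans all landmarks with read-length padding", {
  ctx <- build_splice_context(make_variant(300), three_exon_tx(),
                              max_read_len = 120L)
  expect_equal(ctx$window_start, max(0L, min(100L, 300L, 400L) - 120L))
  expect_equal(ctx$window_end, 400L + 120L)
})

test_that("mirrored gene models give mirrored contexts", {
  # a minus-strand donor variant mirrors the plus-strand acceptor geometry:
  # direction flips and the skip endpoints swap roles around A
  for (sc_pair in list(
    c("exonic_donor_plus", "exonic_donor_minus"),
    c("intronic_acceptor_plus", "intronic_acceptor_minus")
  )) {
    scs <- geometry_scenarios()[sc_pair]
    c1 <- scenario_ctx(scs[[1]])
    c2 <- scenario_ctx(scs[[2]])
    expect_setequal(c(c1$direction, c2$direction), c("left", "right"))
    expect_equal(abs(c1$B - c1$A), abs(c2$B - c2$A))
    expect_equal(sort(abs(c(c1$D - c1$A, c1$E - c1$A))),
                 sort(abs(c(c2$D - c2$A, c2$E - c2$A))))
  }
})
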