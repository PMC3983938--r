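test_that("scenario annotation round-trips through the refGene writer", {
  sc <- splice_scenario()
  lines <- write_refgene(sc$transcripts)
  back <- read_refgene(lines)
  expect_equal(back$exons, sc$transcripts$exons)
  expect_equal(back$gene_symbol, sc$transcripts$gene_symbol)
  expect_equal(back$n_exons, 3L)
})

test_that("planted reads classify into exactly their intended categories", {
  for (name in names(geometry_scenarios())) {
    sc <- geometry_scenarios()[[name]]
    ctx <- scenario_ctx(sc)
    planted <- c(cs_js = 4, es_js = 3, ii_js = 5, ii_ra = 6,
                 normal_splice = 7)
    planted <- c(planted,
                 if (identical(ctx$diff_mode, "spliced_in")) c(cs_ra = 2)
                 else c(anti_cryptic = 2))
    set.seed(77)
    recs <- simulate_reads(sc, counts = planted, mutant_fraction = 1)
    reads <- tibble::tibble(
      read_id = recs$qname,
      blocks = cigar_blocks(recs$cigar, recs$pos0)
    )
    got <- classify_reads(reads, ctx)
    got_cat <- spliceverify:::classification_category(got$consequence,
                                                      got$evidence)
    expect_equal(got_cat, recs$category, info = name)
  }
})

test_that("fully mutant junction-spanning inclusion reads all carry the alt base", {
  sc <- geometry_scenarios()$exonic_donor_plus
  ctx <- scenario_ctx(sc)
  set.seed(78)
  recs <- simulate_reads(sc, counts = c(ii_js = 5), mutant_fraction = 1)
  reads <- tibble::tibble(
    read_id = recs$qname,
    blocks = cigar_blocks(recs$cigar, recs$pos0),
    base_at_variant = mapply(read_base_at, recs$cigar, recs$pos0, recs$seq,
                             MoreArgs = list(pos0 = ctx$variant_pos0))
  )
  counts <- count_region(reads, ctx, "S")
  expect_equal(counts$ii_js, 5L)
  expect_equal(counts$ii_jswm, 5L)
})

test_that("a null scenario emits no validating reads", {
  sc <- splice_scenario(planted = c(normal_splice = 10))
  ctx <- scenario_ctx(sc)
  set.seed(79)
  recs <- simulate_reads(sc)
  reads <- tibble::tibble(
    read_id = recs$qname,
    blocks = cigar_blocks(recs$cigar, recs$pos0)
  )
  counts <- count_region(reads, ctx, "S")
  expect_equal(counts$normal_splice, 10L)
  expect_equal(counts$cs_js + counts$cs_ra + counts$es_js +
                 counts$ii_js + counts$ii_ra, 0L)
})

test_that("impossible plants are rejected", {
  no_flank <- splice_scenario(variant_exon = 1L)
  set.seed(80)
  expect_error(simulate_reads(no_flank, counts = c(es_js = 1)),
               "no flanking exon")
  natural <- splice_scenario()
  expect_error(simulate_reads(natural, counts = c(cs_js = 1)),
               "non-cryptic")
  truncating <- splice_scenario(variant_class = "cryptic",
                                cryptic_side = "exon")
  expect_error(simulate_reads(truncating, counts = c(cs_ra = 1)),
               "spliced-in")
})

test_that("cohort trees are deterministic in the seed and pass BAM validity", {
  sc <- splice_scenario(n_experimental = 3, n_normals = 2,
                        planted = c(ii_ra = 10, normal_splice = 8),
                        control_means = c(normal_splice = 8, ii_ra = 2))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  co1 <- build_cohort(sc, d1, seed = 5)
  co2 <- build_cohort(sc, d2, seed = 5)
  expect_equal(readLines(co1$variants), readLines(co2$variants))
  expect_equal(readLines(co1$annotation), readLines(co2$annotation))
  for (i in seq_len(nrow(co1$experimental))) {
    r1 <- Rsamtools::scanBam(co1$experimental$path[i])[[1]]
    r2 <- Rsamtools::scanBam(co2$experimental$path[i])[[1]]
    expect_equal(r1$qname, r2$qname)
    expect_equal(r1$pos, r2$pos)
    expect_equal(r1$cigar, r2$cigar)
  }
  # sorted + indexed: the index exists and region queries work
  expect_true(all(file.exists(paste0(co1$experimental$path, ".bai"))))
  ctx <- scenario_ctx(sc)
  reads <- fetch_reads(co1$experimental$path[1], sc$chrom,
                       ctx$window_start, ctx$window_end,
                       variant_pos0 = ctx$variant_pos0)
  expect_gt(nrow(reads), 0)
})

test_that("control category counts follow the scenario's Poisson model", {
  sc <- splice_scenario(n_experimental = 1, n_normals = 100,
                        control_means = c(ii_ra = 4, normal_splice = 2))
  d <- withr::local_tempdir()
  co <- build_cohort(sc, d, seed = 31)
  ctx <- scenario_ctx(sc)
  counts <- vapply(co$normals$path, function(p) {
    reads <- fetch_reads(p, sc$chrom, ctx$window_start, ctx$window_end)
    count_region(reads, ctx, "x")$ii_ra
  }, integer(1))
  # empirical mean within 3 standard errors of the Poisson mean
  se <- sqrt(4 / length(counts))
  expect_lt(abs(mean(counts) - 4), 3 * se)
})
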