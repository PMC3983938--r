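test_that("cigar_blocks derives reference blocks from standard alignments", {
  expect_equal(cigar_blocks("30M", 100L)[[1]],
               cbind(start = 100L, end = 130L))
  expect_equal(cigar_blocks("20M100N20M", 80L)[[1]],
               cbind(start = c(80L, 200L), end = c(100L, 220L)))
  # insertions and soft clips consume no reference; deletions extend a block
  expect_equal(cigar_blocks("10M5I10M", 50L)[[1]],
               cbind(start = 50L, end = 70L))
  expect_equal(cigar_blocks("5S10M2D10M", 50L)[[1]],
               cbind(start = 50L, end = 72L))
  expect_error(cigar_blocks("10Q", 0L), "invalid CIGAR")
})

test_that("the six canonical read geometries classify as forced", {
  ctx <- canonical_context()
  reads <- read_tbl(
    c(90, 120),               # contiguous over A
    c(130, 170),              # wholly intronic
    rbind(c(60, 100), c(400, 440)),   # split D -> E
    rbind(c(120, 150), c(200, 230)),  # split J -> B
    c(110, 140),              # inside spliced-in differential region
    rbind(c(70, 100), c(200, 230))    # split exactly at the natural junction
  )
  got <- classify_reads(reads, ctx)
  expect_equal(got$consequence,
               c("intron_inclusion", "intron_inclusion", "exon_skipping",
                 "cryptic", "cryptic", "normal_splice"))
  expect_equal(got$evidence,
               c("junction_spanning", "read_abundance", "junction_spanning",
                 "junction_spanning", "read_abundance", "not_applicable"))
})

test_that("gap-length-only mode admits shifted cryptic splits", {
  ctx <- canonical_context()
  shifted <- read_tbl(rbind(c(125, 155), c(205, 235)))  # gap 50 = B - J
  expect_equal(classify_reads(shifted, ctx)$consequence, "none")
  expect_equal(
    classify_reads(shifted, ctx, strict_cryptic_split = FALSE)$consequence,
    "cryptic"
  )
})

test_that("spliced-out differential regions flip reads to anti-cryptic", {
  ctx <- canonical_context()
  ctx$J <- 60L
  ctx$diff_lo <- 60L
  ctx$diff_hi <- 100L
  ctx$diff_mode <- "spliced_out"
  inside <- read_tbl(c(65, 95))
  expect_equal(classify_reads(inside, ctx)$consequence, "anti_cryptic")
  # and the read fraction uses them as the denominator
  counts <- count_region(
    read_tbl(c(65, 95), rbind(c(50, 60), c(200, 230))), ctx, "S"
  )
  expect_equal(counts$anti_cryptic, 1L)
  expect_equal(counts$cs_js, 1L)
  expect_equal(counts$read_fraction, 1)
})

test_that("mutation carriage requires covering the position with the alt base", {
  expect_equal(read_base_at("10M", 95L, "AAAACTAAAA", 100L), "T")
  expect_equal(read_base_at("10M", 95L, "AAAACGAAAA", 100L), "G")
  expect_true(is.na(read_base_at("10M", 120L, "AAAAAAAAAA", 99L)))
  # position under a deletion or skip is not covered
  expect_true(is.na(read_base_at("4M5D6M", 95L, "AAAAAAAAAA", 101L)))
  expect_true(is.na(read_base_at("4M10N6M", 95L, "AAAAAAAAAA", 101L)))

  ctx <- canonical_context()
  reads <- read_tbl(c(90, 120), c(90, 120))
  reads$base_at_variant <- c("T", "G")
  got <- classify_reads(reads, ctx)
  expect_equal(got$carries_mutation, c(TRUE, FALSE))
})

test_that("count_region aggregates the canonical reads and handles empties", {
  ctx <- canonical_context()
  reads <- read_tbl(
    c(90, 120), c(130, 170),
    rbind(c(60, 100), c(400, 440)),
    rbind(c(120, 150), c(200, 230)),
    c(110, 140),
    rbind(c(70, 100), c(200, 230))
  )
  reads$base_at_variant <- c("T", NA, NA, NA, NA, "G")
  counts <- count_region(reads, ctx, sample_id = "S1")
  expect_equal(counts$ii_js, 1L)
  expect_equal(counts$ii_ra, 1L)
  expect_equal(counts$ii_total, 2L)
  expect_equal(counts$ii_jswm, 1L)
  expect_equal(counts$es_js, 1L)
  expect_equal(counts$cs_js, 1L)
  expect_equal(counts$cs_ra, 1L)
  expect_equal(counts$normal_splice, 1L)
  expect_true(is.na(counts$read_fraction))
  # conservation: every read lands in exactly one bucket
  expect_equal(
    counts$cs_js + counts$cs_ra + counts$es_js + counts$ii_js +
      counts$ii_ra + counts$anti_cryptic + counts$normal_splice + counts$none,
    counts$total_reads
  )
  empty <- count_region(read_tbl(), ctx, "S0")
  expect_equal(empty$total_reads, 0L)
  expect_equal(empty$ii_total, 0L)
})

test_that("reads are counted once per category across isoform contexts", {
  ctx1 <- canonical_context()
  ctx2 <- canonical_context()
  ctx2$transcript_id <- "TX2"
  contexts <- dplyr::bind_rows(ctx1, ctx2)
  reads <- read_tbl(c(90, 120), c(130, 170))
  counts <- count_region(reads, contexts, "S1")
  expect_equal(counts$ii_js, 1L)
  expect_equal(counts$ii_ra, 1L)
  # an isoform with a different skip junction can add a category, but the
  # read still counts once in it
  ctx2$D <- 90L
  ctx2$E <- 120L
  contexts <- dplyr::bind_rows(ctx1, ctx2)
  skip_read <- read_tbl(rbind(c(60, 90), c(120, 150)))
  counts2 <- count_region(skip_read, contexts, "S1")
  expect_equal(counts2$es_js, 1L)
})

test_that("classifier matches the brute-force partition transcription", {
  ctx <- canonical_context()
  set.seed(401)
  reads <- random_reads(ctx, 2000)
  got <- classify_reads(reads, ctx)
  want <- oracle_classify(reads, ctx)
  expect_equal(got$consequence, want$consequence)
  expect_equal(got$evidence, want$evidence)
})

test_that("classification is invariant under coordinate mirror + direction flip", {
  ctx <- canonical_context()
  set.seed(402)
  reads <- random_reads(ctx, 1500)
  got <- classify_reads(reads, ctx)

  A <- ctx$A
  m <- function(x) 2L * A - x
  mirrored_ctx <- ctx
  mirrored_ctx$direction <- "left"
  mirrored_ctx$B <- m(ctx$B)
  mirrored_ctx$D <- m(ctx$E)
  mirrored_ctx$E <- m(ctx$D)
  mirrored_ctx$J <- m(ctx$J)
  mirrored_ctx$diff_lo <- m(ctx$diff_hi)
  mirrored_ctx$diff_hi <- m(ctx$diff_lo)
  mirrored_ctx$intron_start <- m(ctx$intron_end)
  mirrored_ctx$intron_end <- m(ctx$intron_start)
  mirrored_reads <- reads
  mirrored_reads$blocks <- lapply(reads$blocks, function(b) {
    out <- cbind(start = m(b[, "end"]), end = m(b[, "start"]))
    out[rev(seq_len(nrow(out))), , drop = FALSE]
  })
  mirrored <- classify_reads(mirrored_reads, mirrored_ctx)
  expect_equal(mirrored$consequence, got$consequence)
  expect_equal(mirrored$evidence, got$evidence)
})

test_that("classification refuses an unresolved direction", {
  ctx <- canonical_context()
  ctx$direction <- NA_character_
  expect_error(classify_reads(read_tbl(c(90, 120)), ctx), "unresolved")
})
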