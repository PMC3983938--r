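#' Read transcript models from a refGene flat file
#'
#' Parses the UCSC refGene dialect (tab-delimited: bin, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds, ...,
#' name2). Starts are 0-based, ends exclusive, per the UCSC convention; the
#' package keeps that convention internally. Files may be plain or
#' gzip-compressed.
#'
#' RefSeq-based annotation is the intended input: permissive annotation sets
#' with many rare isoforms inflate spurious intron-inclusion calls, because
#' reads that are exonic on the common isoform look intronic on a rare one.
#'
#' @param path Path to a refGene-format file, or a character vector of lines.
#' @return A tibble with one row per exon-bearing transcript:
#'   `gene_symbol`, `transcript_id`, `chromosome`, `strand`, `tx_start`,
#'   `tx_end`, `n_exons`, and a list-column `exons` of two-column integer
#'   matrices (`start`, `end`; 0-based half-open, sorted).
#' @export
read_refgene <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readr::read_lines(path)
  } else {
    path
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      gene_symbol = character(), transcript_id = character(),
      chromosome = character(), strand = character(),
      tx_start = integer(), tx_end = integer(), n_exons = integer(),
      exons = list()
    ))
  }
  rows <- purrr::imap(lines, parse_refgene_line)
  dplyr::bind_rows(rows)
}

parse_refgene_line <- function(line, line_no) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11L) {
    stop(sprintf(
      "refGene parse error at line %d: expected >= 11 tab-separated fields, got %d",
      line_no, length(f)
    ))
  }
  n_exons <- suppressWarnings(as.integer(f[9]))
  starts <- parse_comma_list(f[10])
  ends <- parse_comma_list(f[11])
  if (is.na(n_exons) || length(starts) != n_exons || length(ends) != n_exons) {
    stop(sprintf(
      "refGene parse error at line %d: exonCount (%s) does not match %d exonStarts / %d exonEnds",
      line_no, f[9], length(starts), length(ends)
    ))
  }
  exons <- cbind(start = starts, end = ends)
  if (any(exons[, "end"] <= exons[, "start"]) ||
      is.unsorted(starts, strictly = TRUE) ||
      (n_exons > 1L && any(starts[-1] < ends[-n_exons]))) {
    stop(sprintf(
      "refGene parse error at line %d: exons must be non-overlapping, ordered, non-empty",
      line_no
    ))
  }
  tibble::tibble(
    gene_symbol = if (length(f) >= 13L) f[13] else f[2],
    transcript_id = f[2],
    chromosome = f[3],
    strand = f[4],
    tx_start = as.integer(f[5]),
    tx_end = as.integer(f[6]),
    n_exons = n_exons,
    exons = list(exons)
  )
}

parse_comma_list <- function(x) {
  x <- sub(",+$", "", x)
  if (!nzchar(x)) return(integer())
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Write transcript models back to refGene flat format
#'
#' Inverse of [read_refgene()]: emits the 16-column UCSC layout with dummy
#' values for fields the package does not track (bin, CDS bounds, score,
#' frames).
#'
#' @param transcripts Tibble as returned by [read_refgene()].
#' @param path Output path, or `NULL` to return the lines invisibly.
#' @return The lines, invisibly.
#' @export
write_refgene <- function(transcripts, path = NULL) {
  lines <- purrr::pmap_chr(transcripts, function(gene_symbol, transcript_id,
                                                 chromosome, strand, tx_start,
                                                 tx_end, n_exons, exons, ...) {
    paste(
      0L, transcript_id, chromosome, strand, tx_start, tx_end,
      tx_start, tx_end, n_exons,
      paste0(paste(exons[, "start"], collapse = ","), ","),
      paste0(paste(exons[, "end"], collapse = ","), ","),
      0L, gene_symbol, "unk", "unk",
      paste0(paste(rep("-1", n_exons), collapse = ","), ","),
      sep = "\t"
    )
  })
  if (!is.null(path)) readr::write_lines(lines, path)
  invisible(lines)
}

#' Clean a raw UCSC refGene table dump for use as annotation
#'
#' Takes the table as downloaded from the UCSC table browser (which may carry
#' a `#`-prefixed header line and Windows line endings) and writes a clean
#' headerless refGene file restricted to the standard chromosomes, suitable
#' for [read_refgene()] and the validation pipeline.
#'
#' @param input Path to the raw table (possibly gzipped).
#' @param output Output path.
#' @param keep_chromosomes Regular expression of chromosome names to keep;
#'   the default drops unplaced/alt contigs.
#' @return `output`, invisibly.
#' @export
format_refgene_table <- function(input, output,
                                 keep_chromosomes = "^(chr)?([0-9]+|[XYM]|MT)$") {
  lines <- readr::read_lines(input)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  chrom <- vapply(
    strsplit(lines, "\t", fixed = TRUE),
    function(f) if (length(f) >= 3L) f[3] else NA_character_,
    character(1)
  )
  keep <- !is.na(chrom) & grepl(keep_chromosomes, chrom)
  readr::write_lines(lines[keep], output)
  invisible(output)
}
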