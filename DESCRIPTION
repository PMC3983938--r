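Package: spliceverify
Title: Statistical Validation of Predicted mRNA Splicing Mutations from
    RNA-Seq Read Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Validates DNA-predicted mRNA splicing mutations against bulk
    RNA-Seq alignments. Reads near each predicted variant are classified into
    aberrant-splicing evidence categories (cryptic splice-site use, exon
    skipping, intron inclusion; junction-spanning or read-abundance based)
    and per-sample counts in variant-carrying samples are compared with a
    cohort of non-carrier control samples using a one-sided z-test on
    Yeo-Johnson transformed scores. Includes a refGene annotation parser,
    a synthetic-cohort simulator for fully self-contained testing, power and
    minimum-sample-size helpers, and histogram + Q-Q diagnostics of the
    control read-count distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicAlignments,
    ggplot2,
    IRanges,
    patchwork,
    purrr,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
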