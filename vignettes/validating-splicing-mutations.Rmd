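---
title: "Validating predicted splicing mutations with RNA-Seq read evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating predicted splicing mutations with RNA-Seq read evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceverify)
library(dplyr)
```

## The problem

DNA sequencing of tumours (or any disease cohort) yields large numbers of
variants predicted to damage mRNA splicing: weakening or inactivating a
natural donor/acceptor site, or activating a cryptic site nearby. A
prediction based on sequence alone needs empirical support, and the natural
evidence is the sample's own transcriptome: if the mutation really perturbs
splicing, the RNA-Seq alignments around the affected splice junction should
show aberrant reads — exon skipping, intron retention, or splicing at the
cryptic position — in excess of what non-carrier samples show from ordinary
alternative splicing and noise. Checking this by eye in a genome browser
does not scale past a handful of loci, and eyeballing cannot say whether 14
intronic reads are remarkable or routine.

spliceverify automates the comparison. For each predicted variant it
classifies the aligned reads near the affected splice site in the
variant-carrying sample(s) into evidence categories, counts the same
categories in every non-carrier sample, and asks — per category — whether the
carrier's count is extreme against the control distribution.

## Coordinates and the splice context

Internally all coordinates are 0-based half-open (the BAM convention);
a junction is the position of the first base after the boundary. The
user-facing variant table and output tables are 1-based. For each variant
x transcript isoform the package resolves:

* `A` — the natural splice junction the variant affects (the donor or
  acceptor of the variant's exon or intron);
* the *checking direction* — the side of `A` on which the affected intron
  lies. A donor's intron is 3' of the junction, an acceptor's 5', so the
  genomic direction follows from the site kind and strand. The published
  lookup covers exonic-donor and intronic-acceptor variants; the remaining
  combinations follow the same into-the-intron rule and are flagged in the
  run log (`resolve_direction()`).
* `B` — the natural junction across that intron (the next one in the
  checking direction);
* `D`, `E` — the skip-junction endpoints: the inner boundaries of the exons
  flanking the variant-associated exon. A split read joining `D` to `E` is
  direct evidence that the exon was skipped. A first/last exon has no
  flanking exon on one side; the skip test is then disabled for that
  isoform and the log says so.
* `J` — for cryptic variants, the predicted cryptic junction, and the
  *differential region* between `J` and `A`: the interval whose splicing
  status distinguishes the cryptic isoform from the normal one. When `J`
  lies inside the intron the cryptic isoform retains the region (exon
  extension, "spliced in"); when `J` lies inside the exon the cryptic
  isoform excises it (truncation, "spliced out").

```{r context}
tx <- read_refgene(write_refgene(splice_scenario()$transcripts))
variant <- splice_scenario(variant_class = "cryptic")$variant
build_splice_context(variant, tx[1, ]) |>
  select(direction, A, B, D, E, J, diff_mode)
```

Every isoform of the gene yields its own context; a read validating under
any isoform counts once per category. Left-direction contexts are handled
by reflecting all coordinates (and reads) about `A` and applying the
right-direction predicates — the mirror symmetry of the classification is a
tested invariant, not an assumption.

## Read classification

Reads are fetched over the context window (all landmark coordinates padded
by `max_read_len`, default 1000 bp) with standard filters: mapped, primary,
non-supplementary, non-duplicate, QC-pass, mapping quality at least
`min_mapq` (default 1; missing mapping quality is kept). Paired-end mates
are classified independently. Each alignment's CIGAR is reduced to its
reference blocks; reference skips (`N`) separate blocks, deletions do not.

Each read receives at most one splicing consequence and an evidence type:

| consequence | evidence | test (direction-normalized) |
|---|---|---|
| exon skipping | junction-spanning | split exactly `D` to `E` |
| cryptic | junction-spanning | split exactly `J` to `B` |
| cryptic | read-abundance | contiguous inside a spliced-in differential region |
| intron inclusion | junction-spanning | contiguous over `A` |
| intron inclusion | read-abundance | contiguous wholly within the intron |
| anti-cryptic | — | contiguous inside a spliced-out differential region |
| normal splice | — | split exactly `A` to `B` |

Ties are resolved by ranking junction-defining evidence first: exon
skipping > cryptic > intron inclusion > anti-cryptic > normal splice. Reads
with more than two blocks are evaluated on each adjacent block pair.
Two deliberate interpretation choices are exposed as options:

* the junction-spanning cryptic test defaults to the exact split-point
  form (`strict_cryptic_split = TRUE`); the weaker form that constrains
  only the split gap length (`B - J`) is available, since a gap of the
  right length starting elsewhere is not proof of cryptic-site use;
* reads inside the differential region support the cryptic isoform when
  the region is spliced in (extension) and contradict it when the region
  is spliced out (truncation) — the latter are the anti-cryptic reads, and
  the *read fraction* reports cryptic-supporting over anti-cryptic counts.

`ii_jswm` counts the junction-spanning intron-inclusion reads that carry
the alternate base at the variant position — reads showing the retained
intron on the mutant allele specifically.

## The statistics

Let \(V_j\) be the validated read count of one category in control sample
\(j = 1..N\). The control moments use the population form exactly as
published (divisor \(N\), not \(N-1\)):

\[\mu = \frac{1}{N}\sum_j V_j,\qquad
  \sigma = \sqrt{\tfrac{1}{N}\sum_j (V_j-\mu)^2},\qquad
  z = \frac{|\zeta_x| - \mu}{\sigma},\qquad
  p = P\!\left[Z > \psi(z, \tfrac12)\right]\]

where \(\psi\) is the Yeo-Johnson transform and the tail is the upper
standard-normal tail. With \(\lambda = 1/2\), \(\psi(z, 1/2) \le z\) for
\(z \ge 0\), so the transformed test is *conservative* relative to the raw
z-test — the calibration test in the suite verifies the realized false
positive rate under a Poisson null stays at or below nominal. Counts are
deliberately not normalized across samples; the method relies on a large
control cohort to even out batch effects, and the recommended excess of
controls is at least 5:1.

The surrounding prose of the method can be read as transforming the counts
themselves rather than the z statistic; the formula block above is the only
fully explicit definition, so it is the default (`yj_mode = "zscore"`), and
`yj_mode = "counts"` implements the alternative reading (transform every
\(V_j\) and the observed count, standardize, use the untransformed tail).

p-values are `NA` in two cases, distinguished in the `na_reason` column:
an observed count of zero (no evidence to test) and constant controls
(\(\sigma = 0\), the standardization is undefined). Human-readable tables
print p to two decimals, with values below 0.005 shown as `< 0.01` and
`N/A` for undefined; the machine-readable `results.tsv` keeps full
precision. p-values attach only to consequence-by-evidence categories;
a bare consequence total (like total intron inclusion, `ii_total`) is
reported as a count without a p-value.

```{r stats}
controls <- c(0, 1, 0, 2, 1, 0, 3, 1, 0, 2)
splice_p_value(6, controls) |> select(observed, mu, sigma, z, psi_z, p)
```

A variant is **validated** when any carrier sample reaches `p < alpha`
(default 0.05, strict inequality) in a strongly corroborating category:
junction-spanning cryptic splicing, exon skipping, or intron inclusion, or
read-abundance total intron inclusion. Read-abundance cryptic support and
the mutation-carrying subset corroborate but do not validate on their own.
No multiple-testing correction is applied; `alpha` is exposed for users who
prefer 0.005 or 0.001.

Power planning uses the one-tailed combined quantile
\(z = z_{1-\alpha} + z_{\text{power}}\) (2.4865 for \(\alpha = 0.05\),
power 0.8) and \(N = \lceil \sigma^2 z^2 / ES^2 \rceil\):

```{r power}
combined_power_quantile(0.05, 0.8)
required_sample_size(sigma = 1, effect_size = 0.5)
```

## Cohort handling

Carrier samples come from the variant table's `samples` column (exome-
derived), never from re-genotyping RNA reads. For each variant, every
non-carrier experimental sample plus every normal sample is a control; a
recurrent variant with several carriers scores each carrier against the
same carrier-free control set. Distinct variants hitting the same splice
site are analyzed independently. A coverage advisory is logged when a
carrier has fewer than 20 reads at the locus; it does not gate computation.

## The synthetic-cohort generator

`splice_scenario()` + `build_cohort()` generate everything the pipeline
consumes — refGene annotation, variant table, one sorted+indexed BAM per
sample, BAM list files — with planted read counts per evidence category in
carrier samples and independent Poisson per-category counts in controls.
Default control conditions are 20 normal-splice and 4 intronic reads per
sample at the locus, matching the worked leaky-mutation example's scale
(a carrier with 5 skip and 14 intronic reads against controls averaging
about 4). Reads are minimal single-end records with exact CIGARs and
constant qualities; classification depends only on block structure and the
base at the variant position, which is what the generator controls.

What the generator does *not* emulate: sequencing error and base-quality
structure, fragment-length and strand effects, mapping ambiguity near
paralogs, expression-level variation beyond the per-category Poisson
counts, batch effects, and confounding natural isoforms. Passing the
planted-recovery suite therefore shows the counting and statistics recover
engineered signals at realistic magnitudes; it does not certify behaviour
under alignment artefacts or annotation errors on real data.

```{r cohort}
sc <- splice_scenario(
  n_experimental = 6, n_normals = 4, carriers = 1,
  planted = c(es_js = 5, ii_ra = 14, normal_splice = 70),
  control_means = c(normal_splice = 20, ii_ra = 4)
)
co <- build_cohort(sc, file.path(tempdir(), "vignette_cohort"), seed = 7)
res <- validate_splice_variants(co$variants, co$annotation,
                                co$experimental, co$normals)
tidy(res) |> select(category, observed, mu, sigma, p, significant)
glance(res)
```

`autoplot()` draws the control histogram (Freedman-Diaconis breaks from
Type-8 quantiles) with an embedded normal Q-Q inset of the Yeo-Johnson
transformed control counts, one labelled arrowhead per carrier at its
count, and p-values beneath — significant entries in red. Histograms show
raw counts by default; `transformed = TRUE` switches the axis.

```{r plot, fig.width = 6.5, fig.height = 4.5}
autoplot(res, category = "ii_ra")
```

## Numerical and design choices

* **Coordinates**: 0-based half-open internally; "read wholly within the
  intron" is `start >= A && end <= B`, collapsing the published condition's
  redundant double negation; the implied `start > A - length` is dropped as
  redundant.
* **Nearest-site ties**: the context is anchored on the variant's stated
  `site_kind`, so a variant equidistant from two junctions resolves to the
  annotated site of its stated kind.
* **Degenerate inputs**: empty read sets give all-zero counts; empty
  control cohorts give `NA` statistics with a log note; histogram binning
  of constant data falls back to a single bin with a message.
* **Determinism**: the pipeline itself uses no randomness, so a fixed
  cohort gives byte-identical machine outputs; the generator is a
  deterministic function of (scenario, seed).
* **Test problem sizes**: calibration uses 500 controls x 2000 replicates
  of a Poisson(5) null; planted-signal recovery uses 20 cohorts of 104
  controls with a 10x intron-inclusion excess, and a 20-variant null
  cohort; the classifier is checked against an independent brute-force
  transcription of the partition definitions on 10,000 randomized reads in
  each of the four direction/strand geometries. These sizes give stable
  pass/fail behaviour at desk scale.

## Limitations

* RefSeq-style conservative annotation is assumed; permissive isoform sets
  make exonic reads look intronic on rare isoforms and inflate intron-
  inclusion calls.
* Classification trusts the given alignments — no realignment or de novo
  junction discovery; soft-clipped cryptic junctions that the aligner did
  not split will be missed.
* Indirect skipping evidence (e.g. loss of heterozygosity) is deliberately
  not used.
* Failure to validate is not evidence the prediction is wrong: low
  expression, nonsense-mediated decay, paralogous mapping and confounding
  isoforms all suppress the signal.
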