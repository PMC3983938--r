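# spliceverify

Statistical validation of DNA-predicted mRNA splicing mutations from
RNA-Seq read evidence.

Splicing-mutation predictors (information-theoretic or otherwise) emit far
more candidate variants than anyone can inspect in a genome browser.
spliceverify is for the analyst holding (a) a table of predicted splicing
variants with their carrier samples, (b) a RefSeq-style exome annotation,
and (c) coordinate-sorted, indexed RNA-Seq BAMs for the carrier cohort and
(optionally) normals, who wants each prediction confirmed or left
unsupported by the transcriptome — with a defensible p-value, not a
screenshot.

## The method

For each variant x isoform the package resolves the affected natural
junction `A`, the checking direction (into the adjacent intron), the next
junction `B` across that intron, the skip-junction endpoints `D`/`E`, and
the cryptic junction `J` with its differential region when the variant
activates a cryptic site. Every read near the locus is classified into at
most one evidence category:

* **CS** (cryptic splicing), junction-spanning (split `J -> B`) or
  read-abundance (inside a spliced-in differential region);
* **ES** (exon skipping), junction-spanning only (split `D -> E`);
* **II** (intron inclusion), junction-spanning (contiguous over `A`) or
  read-abundance (wholly intronic), with the mutation-carrying subset
  (JSwM) tracked separately;
* anti-cryptic and normal-splice reads are tallied as contradicting
  evidence and background.

Per category, the carrier's count `|ζ_x|` is tested against the per-sample
counts `V_j` of all `N` non-carrier samples:

    μ = Σ V_j / N        σ = sqrt( Σ (V_j − μ)² / N )
    z = (|ζ_x| − μ) / σ  p = P[ Z > ψ(z, ½) ]

where `ψ` is the Yeo-Johnson transform (λ = ½), making the one-sided test
conservative for right-skewed control counts. A variant is validated when
any carrier reaches `p < 0.05` (configurable) in a strongly corroborating
category (junction-spanning CS/ES/II, or read-abundance total II). Power
planning uses `N = ⌈σ²z²/ES²⌉` with `z = 2.4865` for α = 0.05, power 0.8.

## Worked example

Everything below is synthetic and self-contained: the generator writes the
annotation, variant table, and indexed per-sample BAMs that the validator
then consumes unchanged.

```r
library(spliceverify)

# a leaky-style acceptor variant: carrier shows 5 exon-skipping and
# 14 intronic reads; 9 controls average ~4 intronic reads at the locus
sc <- splice_scenario(
  site_kind = "acceptor", region = "intronic", variant_exon = 2,
  n_experimental = 6, n_normals = 4, carriers = 1,
  planted = c(es_js = 5, ii_ra = 14, normal_splice = 70),
  control_means = c(normal_splice = 20, ii_ra = 4)
)
co  <- build_cohort(sc, "cohort_demo", seed = 42)
res <- validate_splice_variants(co$variants, co$annotation,
                                co$experimental, co$normals)
res
#> <splice_validation>
#>   1 variant(s); 1 validated at p < 0.05
#>   1 carrier sample(s); up to 9 controls per variant
#>   significant strong-category results:
#>     variant_id sample_id category observed           p
#>    chrS:450G>T  TUMOR001    ii_ra       14 0.004650406

dplyr::select(tidy(res), category, observed, mu, sigma, z, psi_z, p)
#> # A tibble: 6 × 7
#>   category observed    mu sigma     z psi_z        p
#> 1 cs_js           0     0  0    NA    NA    NA
#> 2 cs_ra           0     0  0    NA    NA    NA
#> 3 es_js           5     0  0    NA    NA    NA
#> 4 ii_js           0     0  0    NA    NA    NA
#> 5 ii_jswm         0     0  0    NA    NA    NA
#> 6 ii_ra          14  4.78  2.15  4.29  2.60  0.00465
```

The carrier's 14 intronic reads sit 4.3 control standard deviations above
the control mean of 4.8; after the Yeo-Johnson transform the one-sided
p-value is 0.005, so read-abundance intron inclusion — a strong category —
validates the variant. The 5 skip reads get `p = NA` here because no
control sample showed any skip read (σ = 0): with only 9 controls the
category is untestable, which is exactly why a large control cohort is
recommended (≥ 5:1). `write_validation(res, "out/")` writes the
experimental and control count tables (p-values in parentheses), the
full-precision `results.tsv`, the run log, a summary, and the filtered
validated-variant file in the input dialect; `autoplot(res)` draws the
control histogram with embedded Q-Q inset and carrier arrowheads.

A thin CLI over the same functions lives at `inst/cli/spliceverify.R`
(`validate`, `plot`, `synth` subcommands).

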