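# epidrift

Tissue-unique DNA methylation sites and epigenetic information loss.

`epidrift` quantifies how an organ's tissue-specific DNA methylation
signature erodes as its function declines, with the kidney and chronic
kidney disease (CKD) as the motivating system. It is aimed at
epigenomics researchers working with Illumina 450K/EPIC-style beta-value
matrices, a multi-tissue methylation atlas, and clinical phenotypes such
as estimated glomerular filtration rate (eGFR) and interstitial fibrosis
(IF).

## The method

Four stages, each usable on its own:

1. **Correlation scan.** For every CpG probe, the Pearson correlation
   *r* between beta values and a continuous phenotype over
   pairwise-complete samples, with

   *t* = *r*·√(*n* − 2) / √(1 − *r*²),

   a two-sided p-value from the Student *t* distribution with *n* − 2
   degrees of freedom, and Bonferroni control (`pearson_scan`,
   `t_and_p`, `bonferroni`, `partial_correlation`).

2. **Tissue-unique site calling.** A probe is unique in the target
   tissue when its mean beta there lies at least δ = 0.2 *below* the 5%
   quantile of all other tissues' samples pooled (under-methylated) or
   at least 0.2 *above* their 95% quantile (over-methylated), after
   removing probes with too few non-missing values
   (`call_unique_sites`). Each site gets a signed *uniqueness* distance:
   pooled non-target median minus target mean (`uniqueness_score`).

3. **Drift toward the common baseline.** For each unique site, mean
   beta in low-fibrosis (IF < 20) versus high-fibrosis (IF > 20)
   samples, a flag for whether the change points toward the
   cross-tissue common level, an exact one-sided sign test computed in
   log space (`group_drift`, `sign_test`), hypergeometric enrichment of
   unique sites among the top IF-correlated decile
   (`overlap_enrichment`, `top_fraction`), and the correlation between
   uniqueness and correlation-to-IF (`uniqueness_vs_if`).

4. **Information-loss score.** Per sample, the number of unique sites
   whose beta value has moved from the healthy-reference median toward
   the common baseline by at least *k* = 2 reference standard
   deviations; deviations away from the baseline never count
   (`build_reference`, `information_loss_score`, `score_cohort`).

A synthetic-data module (`synth_config`, `generate_atlas`,
`generate_kidney_cohort`) generates multi-tissue atlases with planted
unique sites and fibrosis-graded kidney cohorts with full ground truth,
and `run_pipeline` composes all stages.

## Worked example

```r
library(epidrift)

cfg <- synth_config(seed = 1L)           # 5 tissues x 20 samples, 5,000 probes
gen <- generate_atlas(cfg)               # atlas + ground truth
cohort <- generate_kidney_cohort(gen$truth, 100, cfg)

calls <- call_unique_sites(gen$atlas, "kidney")
classify_directions(calls)
#> n_under  n_over
#>      49      10

drift <- group_drift(cohort$matrix, cohort$sheet, calls, if_threshold = 20)
sign_test(sum(drift$toward_common, na.rm = TRUE),
          sum(!is.na(drift$toward_common)))$log10_p
#> [1] -17.76077

ref <- build_reference(cohort$matrix, cohort$sheet, calls)
res <- score_cohort(cohort$matrix, cohort$sheet, ref, k = 2)
res$correlations
#>   phenotype          r            p   n
#> 1        IF  0.9733200 1.838643e-64 100
#> 2      eGFR -0.8588655 3.125611e-30 100
```

All 59 recovered unique sites (of 60 planted) drift toward the common
baseline as fibrosis rises (one-sided sign test, log10 p ≈ −17.8), and
the per-sample information-loss score rises with fibrosis (r ≈ 0.97)
while falling with kidney function (r ≈ −0.86) — the qualitative
pattern expected when tissue identity erodes with disease.

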