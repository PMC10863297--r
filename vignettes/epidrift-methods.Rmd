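---
title: "Methods: quantifying the loss of tissue-unique methylation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the loss of tissue-unique methylation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidrift)
```

## The scientific question

Every tissue carries a characteristic DNA methylation signature: a small
set of CpG sites whose methylation in that tissue lies far outside the
range seen anywhere else in the body. `epidrift` asks whether, and how
fast, that signature erodes as organ function declines — using the
kidney as the model system, with estimated glomerular filtration rate
(eGFR, mL/min/1.73m²; lower is worse) and interstitial fibrosis (IF,
percent of fibrotic interstitium; higher is worse) as the clinical
axes. The package's working hypothesis is directional: in diseased
tissue, unique sites do not wander randomly but *regress toward the
cross-tissue common baseline*, i.e. tissue identity information is
lost, not merely perturbed.

## The model, stage by stage

### Per-CpG phenotype scan

For each probe, the Pearson correlation $r$ between its beta values and
the phenotype is computed over pairwise-complete observations — each
probe uses every sample where both its own value and the phenotype are
present. This mirrors per-site EWAS practice and maximizes the per-probe
sample size under missingness; the alternative (listwise deletion across
the whole matrix) discards samples because of missingness at unrelated
probes. Significance comes from

$$t = \frac{r\sqrt{n-2}}{\sqrt{1-r^2}}, \qquad p = 2\,P(T_{n-2} \ge |t|),$$

with Bonferroni control using $m$ = the number of probes actually
tested (after the `min_pairs` and zero-variance filters), not the array
size. Perfect fits ($|r| = 1$) have no finite $t$; they are returned
with $p = 0$ and an `exact_fit` flag rather than silently clamped.
Partial correlations (for covariate adjustment, e.g. age or BMI) are
computed as the correlation of QR residuals of both variables on the
covariates, which is algebraically equivalent to the recursive
first-order formula. Sex-stratified analyses are plain re-runs on
subset sample sheets; no special code path exists.

### Tissue-unique site calling

A probe is *unique-under* in the target tissue when its mean beta there
is lower by at least $\delta$ than the $q$ quantile of all non-target
samples pooled, and *unique-over* when it is higher by at least
$\delta$ than their $1-q$ quantile. Defaults $\delta = 0.2$, $q = 0.05$:
the 0.2 margin is a conventional effect-size floor for a biologically
meaningful methylation difference, and the 5%/95% tails tolerate a
small minority of outlying non-target samples without surrendering the
call. Pooling all non-target samples (rather than per-tissue means) is
the primary mode because the rule is stated against "all other
samples"; a per-tissue-mean mode (`per_tissue_quantiles = TRUE`) is
kept for sensitivity analysis, since with unbalanced atlases the pooled
quantile is dominated by the well-sampled tissues. Probes with fewer
than `min_values` non-missing values across the atlas are removed
before calling: 2000 at the scale of public multi-tissue references,
scaled to `ceiling(0.7 * n_samples)` for smaller data.

Each called site gets a signed **uniqueness** distance: pooled
non-target *median* minus target mean. The paper-scale analyses never
pin down this distance formally, so the package fixes it as the median
gap — robust to outlier tissues, positive for under-methylated sites —
and records the convention in the call metadata so alternates (e.g.
nearest-quantile gap) can be swapped without ambiguity.

### Drift toward the common baseline

Samples are split at `if_threshold = 20` percent fibrosis (strict
inequalities; samples exactly at the threshold are excluded). For each
unique site, the flag

`toward_common = sign(mean_high - mean_low) == sign(baseline - mean_low)`

records whether the high-fibrosis group moved toward the cross-tissue
common level. Under the null of direction-free change the flags are
fair coins, so global concordance is tested with the exact one-sided
binomial sign test $P(X \ge k)$, $X \sim \mathrm{Bin}(n, 1/2)$. Both the
sign test and the hypergeometric overlap enrichment are computed via
`pbinom`/`phyper` with `log.p = TRUE` and reported in log10 alongside
the linear scale, because fully concordant sets of a few hundred sites
produce tails ($10^{-87}$ at $n = 289$) far below double-precision
underflow.

### The information-loss score

Per called site, a reference median and standard deviation (sample SD,
$n-1$ denominator — the reference sets are small) are computed over a
reference population, with the direction from that median toward the
common baseline. A sample's score is the count of sites where

$$(\beta - \tilde\beta_{\mathrm{ref}}) \cdot d \ge k \cdot s_{\mathrm{ref}},$$

with $d = \pm 1$ the baseline direction and $k = 2$ by default. The
comparison is inclusive ("at least $k$ standard deviations"), and
deviations *away* from the baseline never count, whatever their
magnitude — the score measures directed information loss, not
variability. Missing values shrink the per-sample eligible set, so the
score is reported both as a raw count and as a fraction of eligible
sites.

The reference population is genuinely ambiguous in this kind of design:
the healthy stratum of the clinical cohort, or the atlas's own samples
of the target tissue. The default is the healthiest cohort stratum
(IF < 20), because an SD estimated on the same platform as the scored
samples reflects platform noise rather than cross-study variation; an
atlas reference is available by passing any `reference_rule`. Probes
with zero reference SD are excluded (the threshold would be
meaningless), as are probes whose baseline coincides with the
reference median (no direction).

## The synthetic study

The generator emulates the two data sources the analysis needs, with
full ground truth.

**Noise model.** Every value is drawn from a beta distribution
parameterized by (mean $\mu$, precision $\phi$): shapes $\mu\phi$ and
$(1-\mu)\phi$, so the variance $\mu(1-\mu)/(\phi+1)$ shrinks near 0 and
1, matching the bounded heteroscedastic noise of methylation arrays.
Default $\phi = 50$ gives an SD of about 0.07 at $\mu = 0.5$ and 0.03
near the boundaries — the scale of inter-individual spread on 450K
arrays.

**Atlas.** 5 tissues × 20 samples and 5,000 probes by default. Planted
under-methylated unique sites have a high common baseline (uniform in
[0.80, 0.95]) in all non-kidney tissues and a kidney mean 0.35 below
it; over-methylated sites mirror this. The 50:10 under:over split
echoes the strong predominance of under-methylated unique sites
observed in kidney. The planted offset 0.35 matches the observed
pattern of kidney levels near 0.35 at sites almost completely
methylated elsewhere, and exceeds the 0.2 calling margin so planted
sites are detectable by construction. 100 fibrosis-correlated but
non-unique probes (per-IF slope ±[0.001, 0.002]) and a 2% missingness
rate round out the design.

**Cohort.** IF is uniform over [0, 100]; eGFR = 100 − 0.75·IF +
N(0, 10), truncated at 0, so the two markers move oppositely and the
cohort lands near mean 63 ± 24 — typical of a CKD biopsy series. For
unique probes the expected beta is
$\beta_{\mathrm{kid}} + w\,(\beta_{\mathrm{common}} - \beta_{\mathrm{kid}})$
with $w = \min(1, 0.01 \cdot \mathrm{IF})$: drift linear in fibrosis,
saturating at the common baseline (the observed shift is monotone;
linearity with saturation is the simplest form consistent with it).
One shared seed is split into named substreams (probe truth, atlas
values, phenotypes, cohort values), so adding probes never perturbs the
phenotype draws.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: probe cross-reactivity and
SNP-affected probes, batch and position effects, cell-type composition
and its change with fibrosis (on real kidney, part of the drift signal
reflects shifting cell populations, which this generator collapses into
the per-probe mean), correlated probes within CpG islands, and
non-uniform clinical covariate distributions. Recovery rates and
correlation magnitudes on synthetic data are therefore upper bounds on
what the same thresholds achieve on arrays.

## Numerical choices

- Quantiles: `stats::quantile` type 7 (linear interpolation between
  order statistics), pinned and recorded in the call metadata.
- Beta values within 1e-9 of the [0, 1] bounds are clamped; anything
  further out is an input error. Missing markers in files: empty cells,
  `NA`, `NaN`, or any non-numeric token.
- Tail probabilities in log space throughout; the linear `p` is exact
  `exp(log p)` and may underflow to 0, `log10_p` never does.
- `pearson_scan` computes all probes in one vectorized pass over
  indicator-masked cross-products; it is tested to 1e-12 against a
  naive per-probe `cor.test` loop.
- Ties in `top_fraction` break lexicographically by probe id;
  `align_samples` orders canonically by sample id — both so repeated
  runs are byte-identical.
- Degenerate inputs fail loudly: constant phenotypes, empty selections,
  all-missing samples, and undefined correlations raise errors rather
  than returning NaN.

## Problem sizes

The test suite runs the full default study (5,000 probes, 100 atlas
samples, 100-sample cohort) for the end-to-end checks and an 800-probe
configuration for unit tests; both complete in seconds. The
acceptance script repeats the default study from scratch at a
user-supplied seed.

## Known limitations

- The pipeline correlates user-supplied phenotypes only; epigenetic
  clock values are treated as ordinary phenotype columns, never
  computed.
- Single-probe calls only: no merging of adjacent probes into regions,
  and sites unique in several tissues at once are not modeled.
- The sign test treats sites as independent; on real arrays,
  neighboring unique sites within one island are correlated, so the
  printed tail probabilities are anti-conservative there.
- Bonferroni is the only multiplicity control offered, by design.
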