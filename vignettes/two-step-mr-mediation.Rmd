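---
title: "Two-step Mendelian randomization with a mediated path: models, choices, and operating characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step MR mediation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem and the model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure $X$ on an outcome $Y$ from two independent GWAS: per-variant
effects $\hat\beta_{Xj}$ (with standard error $\sigma_{Xj}$) on the
exposure and $\hat\beta_{Yj}$ (with $\sigma_{Yj}$) on the outcome, for a
set of instrument SNPs $j = 1,\dots,k$. Each instrument must be strongly
associated with the exposure, independent of confounders, and affect the
outcome only through the exposure. Under those assumptions every variant
supplies a Wald ratio $\hat r_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with
first-order standard error $s_j = \sigma_{Yj}/|\hat\beta_{Xj}|$, and the
estimators differ only in how they pool the ratios:

* **IVW**: $\hat B = \sum w_j \hat r_j / \sum w_j$ with $w_j = 1/s_j^2$;
  fixed-effects SE $(\sum w_j)^{-1/2}$, inflated multiplicatively by
  $\max\{1, \sqrt{Q/(k-1)}\}$ under the random-effects model. The default
  `auto` rule uses random effects exactly when Cochran's
  $Q = \sum w_j(\hat r_j - \hat B)^2$ rejects at $p < 0.05$.
* **MR-Egger**: weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ *with an intercept* (weights $1/\sigma_{Yj}^2$, pairs
  oriented so $\hat\beta_{Xj} \ge 0$). The slope estimates the causal
  effect under the weaker InSIDE assumption; the intercept estimates
  directional pleiotropy and feeds the pleiotropy test.
* **Weighted median**: the 0.5-crossing of the cumulative standardized
  inverse-variance weights over the ordered ratios (midpoint convention,
  linear interpolation); valid when at least half the weight is valid.
* **Simple/weighted mode**: the argmax of a normal-kernel density over
  the ratios with bandwidth $\phi \cdot 0.9\,\min(\mathrm{sd},
  \mathrm{IQR}/1.349)\,k^{-1/5}$, weights uniform or inverse-variance;
  valid when the largest homogeneous cluster is valid.

Median and mode standard errors come from a seeded parametric bootstrap
(resampling each $\hat\beta$ from its sampling distribution); p-values
are two-sided normal for all five estimators. Binary outcomes are
analysed on the log-odds scale and reported as $OR = e^B$ with
$e^{B \pm 1.96\,SE}$ limits.

A direction is *called* causal by three rules applied together: the five
effect estimates agree in sign; the IVW p-value is below 0.05 (no
multiple-testing correction anywhere — the workflow is explicitly
exploratory); and OR above/below 1 classifies risk versus protection.

## Two-step mediation

For an exposure → mediator → outcome path the package estimates

* **Stage 1** ($B_1$, $S_1$): the exposure's effect on the mediator,
  either by two-stage least squares on an individual-level cohort
  (regress exposure on instrument dosages, then the mediator on the
  fitted exposure; t-based inference with $n-2$ df) or, when only summary
  statistics exist, by an intercept-including weighted regression of
  mediator-side effects on exposure-side effects (weights
  $1/\sigma^2_{Mj}$, $k-2$ df). Both report the same table shape
  (intercept row, predicted row, $t = B/S$, $R^2$).
* **Stage 2** ($B_2$, $S_2$): the mediator's effect on the outcome from
  the IVW estimator over the mediator's instruments; the report records
  whether the fixed- or random-effects model supplied it.
* **Mediated effect**: the product of coefficients with Sobel's standard
  error,
  $B_m = B_1 B_2$, $S_m = \sqrt{B_1^2 S_2^2 + B_2^2 S_1^2}$,
  $Z = B_m/S_m$, two-sided normal $P_m$, and $B_m \pm 1.96\,S_m$ limits.
  The normal approximation matches the printed-report convention; a
  Monte-Carlo check of the product distribution in the test suite shows
  the approximation is accurate when either stage is well-determined.

A bundled worked example (`worked_example_tables()`) carries the stage-1
coefficient table of seven lipid exposures on leukocyte telomere length
and the corresponding mediation table against cancer outcomes; feeding
the printed stage-1 slopes and the lung-path log-OR ($\log 1.411$)
through `sobel_mediation()` reproduces the printed $B_m$ rows to three
significant figures, and $B_m/S_m$ reproduces the printed $Z$ values.

## Instrument selection and QC

The selection funnel (all thresholds in `selection_config()`, echoed into
the run manifest): exposure association $p < 5\times 10^{-8}$; greedy
clumping at $r^2 = 0.001$ within 10,000 kb (when no LD matrix is
supplied, all same-window pairs are treated as linked — distance-only
thinning, exact for the independent-SNP simulations); instrument
strength $F = (\beta/\sigma)^2 > 10$, with variance explained
$r^2 = F/(F+n-2)$; removal of variants on a user-supplied confounder
exclusion list (the stand-in for a phenome-wide lookup, matched by
variant id only); and removal of variants associated with the outcome at
$p < 10^{-5}$. Every filter marks rather than discards, so
input = kept + dropped-by-reason holds exactly per direction.

Harmonization aligns outcome effects onto the exposure's effect allele,
complementing strands where needed. Palindromic variants default to
frequency inference with an ambiguous band of eaf $\in (0.42, 0.58)$
(`policy = "drop"` is available); this mirrors common two-sample MR
practice, since no action is mandated by the workflow we reproduce.
Missing allele frequencies can be completed from a reference table,
complementing when the reference is keyed to the other allele.

## Sensitivity diagnostics

Cochran's Q (with the fixed/random IVW switch), the Egger intercept test
(p < 0.05), and Steiger directionality: instrument $r^2$ summed per side
from the F approximation, direction correct when the exposure side
explains more, p from a two-sample z-test of Fisher-transformed
correlations. For binary outcomes the same $r^2$ approximation is applied
on the log-odds scale and documented as an approximation.

**MR-PRESSO.** The global test simulates the no-pleiotropy null: observed
RSS $\sum_j (\hat\beta_{Yj} - \hat b_{(-j)}\hat\beta_{Xj})^2$ with
leave-one-out IVW slopes $\hat b_{(-j)}$, compared to `n_sim` simulated
datasets in which *both* betas are resampled and the leave-one-out slopes
recomputed. Recomputing the slopes inside each simulation matters: a null
that conditions on the observed slopes lacks the slope-estimation noise
the observed RSS contains and over-rejects (we measured ~0.10 at nominal
0.05; the faithful version sits near 0.045). Per-variant outliers are
flagged at the Bonferroni level $\alpha/k$; `remove_outliers()` plus the
reported pre/post estimates form the optional distortion information.

**Sample overlap.** `overlap_bias()` implements the standard
approximation: expected bias = overlap proportion × confounded
observational effect / mean instrument F, with the induced type-I error
from a shifted normal. All three inputs are explicit configuration — no
formula for this appears in the workflow we reproduce, so the function
follows the two-sample overlap literature.

## The synthetic-data generator

`sim_config()` / `simulate_cohort()` emulate the structure of the real
inputs: independent biallelic SNPs (maf uniform on 0.05–0.5,
non-palindromic allele pairs, spread across chromosomes at 20 Mb spacing
so distance-clumping keeps them all), a quantitative exposure and
mediator with unit variance in expectation, and a binary outcome.
Defaults are fixed at values a practitioner would call realistic for
lipid-like traits: 50 instruments per trait with per-SNP effects of sd
0.09 (about 15% heritability, matching large lipid GWAS), GWAS samples of
20,000, outcome prevalence 0.1.

Design choices worth stating explicitly:

* **Log-odds liability.** The outcome thresholds a liability with
  *standard-logistic* noise, so the configured `effect_m_to_y` and
  `direct_x_to_y` are exact conditional log-odds. A Gaussian liability
  would make the marginal logistic betas ~1.5–1.6× the configured value
  and break any recovery comparison on the log-odds scale. The remaining
  gap between conditional and marginal log-odds (noncollapsibility) is a
  few percent at these effect sizes and is a property of the estimand,
  not of the code.
* **Mediator instruments.** The mediator has its own instrument SNPs
  (`n_snps_mediator`, disjoint from the exposure panel). Without them the
  mediator's only genetic signal would be $a\gamma$, far too weak to
  reach genome-wide significance, and the mediator → outcome step of the
  two-step design could never be instrumented. Exposure-SNP → mediator
  and exposure-SNP → outcome pleiotropy remain separate knobs.
* **Directional pleiotropy is oriented.** A directional mean for the
  SNP → outcome effects is applied relative to the exposure-increasing
  allele; under arbitrary allele coding a fixed mean would cancel after
  the Egger orientation and be undetectable by construction.
* **Overlap and confounding.** A shared latent standard normal loads on
  exposure and liability with configurable coefficients; overlapping
  exposure/outcome subsamples share individuals (and hence estimation
  errors), which is the mechanism of overlap bias.
* Scans are closed-form per-SNP OLS for quantitative traits and per-SNP
  logistic regression for the outcome; underflowed p-values are clamped
  at `1e-300` so genome-wide hits survive record validation. A
  summary-level fast route (`simulate_summary_gwas()`) draws the betas
  directly from their asymptotic sampling distributions for large
  replicate studies; it refuses configurations (overlap, confounding) it
  cannot represent.

What passing simulation tests do *not* show: the generator has no LD
(it emulates the post-clumping state), no population stratification, no
case-control ascertainment beyond prevalence thresholding, and no
heterogeneous trait architectures, so real-data behaviour of clumping
against an LD panel or of pleiotropy-robust estimators under realistic
architectures is out of its reach.

## Operating characteristics (what the experiments compute)

The `experiment_*` functions reproduce the package's calibration and
recovery claims; problem sizes were chosen so each study is decisive at
its replicate count while the whole suite stays desk-scale.

* **Null calibration** (1000 replicates, 50 SNPs/trait, n = 100,000):
  mediated null with `a = 0` but `b = 0.4`. The Sobel statistic is known
  to be far below its nominal level when *both* stages are null (the
  product of two null normals is not normal); the standard condition
  under which its level is interpretable keeps one stage real, which is
  what a mediated-null study means here. The IVW leg of this experiment
  calibrates the fixed-effects test on its homogeneous null; the `auto`
  rule is deliberately conservative under the null because its
  random-effects branch triggers on the 5% of replicates with large Q.
  Both rates sit near 0.05 (measured 0.053/0.056 at 4000 replicates).
* **MR-PRESSO calibration** (200 replicates): global-test rejection on
  clean data, ~0.045.
* **Recovery** (100 replicates, n = 20,000, 50 SNPs/trait, a = 0.3,
  b = 0.4): full cohort simulation, genome-wide instrument selection,
  2SLS stage 1 on the mediator cohort, IVW stage 2, Sobel interval
  checked against the true mediated effect 0.12. The mean recovered
  effect sits ~4–6% below the truth — winner's curse on the stage-2
  denominators plus noncollapsibility — which is the known behaviour of
  this estimand, and the 95% interval covers the truth in ≥ 93% of
  replicates.
* **Overlap** (250 replicates/level at overlap 0, 0.5, 1): deliberately
  weak instruments (mean F ≈ 25 after selection at `p < 1e-3`; at
  genome-wide stringency this regime selects nothing) and a strong shared
  confounder (loadings 0.8 on the exposure, 3 on the liability, balanced
  prevalence). Type-I error of the exposure → outcome IVW test rises
  monotonically with overlap (about 0.05 → 0.10 → 0.22), the qualitative
  overlap-bias pattern.

## Numerical conventions and degenerate inputs

Ties in clumping break deterministically by (p-value, variant id); the
weighted-median crossing uses the midpoint convention; a zero mode
bandwidth (all ratios identical) returns the common ratio; `beta_x = 0`
pairs are excluded from ratios with a warning; Egger SEs use
multiplicative inflation clamped below at 1; all bootstraps and
simulations take explicit seeds and restore the caller's RNG state; the
pipeline derives every stream from one global seed, making report files
byte-identical across reruns. Directions that end with fewer than three
usable instruments are marked failed in the report and the pipeline
continues.

## Known limitations

Clumping without an LD matrix is distance-only; exclusion matching is by
variant id (no proxy lookup); Steiger's binary-outcome $r^2$ is an
approximation; the summary-level stage 1 inherits regression dilution
from noisy instrument effects (the 2SLS stage 1 does not); and the
simulator's idealizations listed above. Multivariable MR, proportions
mediated, and figure rendering are intentionally out of scope; the
report tables are plot-ready instead.
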