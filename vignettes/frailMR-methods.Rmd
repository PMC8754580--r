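---
title: "Methods: two-sample MR of serum protein status on the frailty index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR of serum protein status on the frailty index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailMR)
```

## The question and the design

Observational studies suggest that better protein nutritional status (higher
serum albumin, higher serum total protein) protects against frailty, but such
associations are vulnerable to confounding and reverse causation.  Mendelian
randomization (MR) sidesteps both by using genetic variants as instrumental
variables: alleles are randomized at meiosis, so a variant that raises serum
albumin by a known amount acts like a lifelong, confounder-free mini-trial of
higher albumin.

frailMR implements the two-sample summary-data version of this design.  The
exposure side is a set of SNP-albumin (or SNP-total-protein) associations
$\hat\beta_{Xj} \pm \sigma_{Xj}$ (g/L per effect allele) from one GWAS; the
outcome side is the association of the same SNPs with the Rockwood frailty
index (FI), $\hat\beta_{Yj} \pm \sigma_{Yj}$, in FI percentage points per
allele, from age- and sex-adjusted linear regressions in a second sample.
The FI itself is the deficit-accumulation measure: the number of health
deficits present out of a catalogue of $T$ items (here $T = 49$), expressed
as a percentage (`computeFI()`); 10 deficits of 49 give 20.4%.

Under the instrumental-variable assumptions, each SNP yields a ratio (Wald)
estimate of the causal effect $\theta$ (FI % per g/L),
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$, with first-order standard
error $\sigma_{Yj}/|\hat\beta_{Xj}|$ and hence inverse-variance weight
$w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$.

## The five estimators

**Fixed-effect IVW** (`mrIVW()`): the weighted mean
$\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$ with standard error
$(\sum_j w_j)^{-1/2}$, i.e. weighted least squares of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ through the origin with weights $1/\sigma_{Yj}^2$ and no
residual-scale inflation.  Consistent when every instrument is valid.

**Penalized-weight IVW** (`mrPenalizedIVW()`): a one-pass robustification.
Each SNP's heterogeneity contribution $q_j = w_j(\hat\theta_j-\hat\theta)^2$
is referred to the $\chi^2_1$ upper tail, and its weight is multiplied by
$\min(1, 20\,p_j)$.  SNPs whose ratio estimate is consistent with the pooled
value ($p_j \ge 0.05$ with the default scale constant 20) keep their full
weight, so the estimator collapses to plain IVW in the absence of outliers.
The scale constant is exposed as `penaltyScale`.

**Weighted median** (`mrWeightedMedian()`): order the ratio estimates, form
midpoint cumulative ranks $s_j = (\mathrm{cum}_j - w_j/2)/\sum w$, and
interpolate $\hat\theta_{(j)}$ at $s = 0.5$.  Consistent when instruments
carrying at least half the weight are valid.  The standard error comes from a
parametric bootstrap (default 1000 draws) that resamples both
$\hat\beta_{Xj} \sim N(\hat\beta_{Xj}, \sigma_{Xj})$ and
$\hat\beta_{Yj} \sim N(\hat\beta_{Yj}, \sigma_{Yj})$; the point estimate is
deterministic and only the SE depends on the seed.  Ties in the ordering are
broken by SNP identifier so results are reproducible.

**MR-Egger** (`mrEgger()`): weighted least squares of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ with a free intercept and weights $1/\sigma_{Yj}^2$, after
orienting all instruments exposure-positive (`orientPositiveExposure()`,
without which the fit is not well defined).  The slope is a
pleiotropy-adjusted causal estimate; a non-zero intercept indicates
directional pleiotropy and its test is reported alongside.  Standard errors
multiply the normal-equation variances by the dispersion
$\max(1, Q_E/(J-2))$ — the conservative multiplicative random-effects
convention — with $t_{J-2}$ p-values; `dispersion = "fixed"` switches the
inflation off.  The confidence-interval slots keep the package-wide
normal-quantile convention (1.959964), with t-quantile bounds in `extras`.

**MR-Lasso** (`mrLasso()`): augment the IVW regression with one free
intercept $\alpha_j$ per SNP, penalized by $\lambda\sum_j|\alpha_j|$, and
minimize $\sum_j \sigma_{Yj}^{-2}(\hat\beta_{Yj} - \alpha_j -
\theta\hat\beta_{Xj})^2$ by coordinate descent (soft-threshold update for
each $\alpha_j$, IVW update for $\theta$, relative tolerance $10^{-10}$).
SNPs with $\alpha_j = 0$ are the valid set.  The penalty is chosen by a
heterogeneity stopping rule: 50 log-spaced values from $\lambda_{\max}$ (the
closed-form smallest penalty forcing all intercepts to zero) down to
$10^{-4}\lambda_{\max}$ are scanned downward, stopping at the first value
whose valid set has a Cochran Q below the upper-$\alpha$ $\chi^2_{|V|-1}$
critical value; the reported effect is fixed-effect IVW on that valid set
(post-lasso estimator).

The stopping rule's significance level `alphaHet` defaults to 0.01 rather
than 0.05: removing an instrument changes the model, so the package requires
strong rather than borderline evidence of heterogeneity before discarding
one.  Borderline sets — upper-tail probability between 1% and 5%, as for the
bundled albumin instruments, whose Q of 11.71 on 5 df sits at p = 0.039 — are
kept intact; this matches the published selection for the bundled set
(all six SNPs valid, which `reproduceStudy()` recomputes) and keeps
selections stable under small perturbations of the inputs, at the price of
less aggressive outlier removal.  Genuine outliers are far from the
boundary: a direct effect of five outcome-SEs contributes a Q of roughly 25
and is excluded at either level.

## Diagnostics

`cochranQ()` gives instrument-level heterogeneity,
$Q = \sum_j w_j(\hat\theta_j - \hat\theta_{IVW})^2$ on $J-1$ df — identically
the weighted residual sum of squares of the IVW regression.
`strataHeterogeneity()` applies the same construction across stratum
estimates (women vs men), pooling by fixed-effect inverse variance; when only
printed 95% CIs are available, `seFromCI()` recovers the SEs with the normal
quantile, which reproduces published stratum p-values to about ±0.005 (the
original computations used unrounded SEs).  `leaveOneOut()` tabulates
per-SNP influence.

## Harmonization

`harmonize()` joins exposure and outcome records by rsID (intersection; SNPs
absent from either file are dropped, the two-sample convention) and orients
the outcome effect to the exposure's effect allele, flipping the beta sign
and complementing the frequency when the alleles are swapped, allowing for
strand complement.  Palindromic SNPs (A/T, C/G) cannot be oriented from
allele labels; they are resolved by effect-allele-frequency agreement, and
dropped with a warning when either frequency is missing or both lie in the
ambiguity window (default minor-allele band `[0.42, 0.58]`, configurable).
The bundled instrument sets contain no palindromic SNPs; the window matters
only for user-supplied data.

## The synthetic cohort generator

`simulationConfig()`/`twoSampleSummary()` generate individual-level data with
the statistical structure the analysis assumes, so that every stage — the
per-SNP regressions, harmonization, and all five estimators — can be
validated end to end without any external data:

* genotypes: independent biallelic SNPs in Hardy-Weinberg proportions
  (Binomial(2, eaf)); the default panel uses the six bundled albumin
  frequencies and effect sizes;
* exposure: additive genetic score plus normal noise.  The residual SD
  defaults to 0.67 g/L so that the per-SNP exposure SEs at the default
  n = 20,000 match the bundled set's — the simulated instruments have the
  same strength as the real ones;
* frailty index: linear in the exposure (default true effect −0.15 FI % per
  g/L), optional per-SNP direct (pleiotropic) effects, age (N(56.7, 8) years,
  0.25 FI%/year) and sex (53.3% women, +1.5 FI%), plus normal noise scaled so
  the FI has mean ≈ 12% and SD ≈ 7.4%, then clipped to [0, 100];
* two-sample design: disjoint exposure and outcome cohorts from one seed;
  `overlapFraction` deliberately re-uses exposure individuals to study
  overlapping-sample bias.

What the generator does **not** emulate: linkage disequilibrium between
instruments, imputation dosage uncertainty, population stratification or
relatedness, the discrete bounded nature of a real deficit count, and
skewness of the real FI distribution.  Passing recovery tests on this
generator therefore demonstrates correctness of the estimators under the
model's own assumptions, not robustness to those real-data features.

One consequence of the bounded index is worth stating: with mean 12% and SD
7.4%, about 5% of the raw normal FI mass falls below 0 and is clipped, which
attenuates every genotype-FI coefficient by a factor of about 0.95.  The
package's validation suite (200 replicates at n = 20,000 per sample)
accordingly observes a small positive mean bias of about +0.01 on a true
effect of −0.15 for all estimators — a property of the bounded-outcome design
itself, not of the estimators, and one reason the recovery checks on the
noisier estimators (Egger, with a per-replicate SD of about 0.6 at this
sample size) resolve the bias bound only up to Monte-Carlo error.

## Numerical and interface choices

* Confidence intervals use the fixed normal quantile 1.959964 throughout;
  p-values are two-sided (normal for IVW/penalized/median, $t_{J-2}$ for
  Egger).
* First-order weights $\hat\beta_{Xj}^2/\sigma_{Yj}^2$ are the default
  everywhere; `weights = "second"` adds the exposure-side variance term.
* Degenerate inputs fail loudly: zero exposure betas (undefined ratio),
  constant dosage columns, rank-deficient designs, identical exposure betas
  in Egger (singular), empty harmonized sets.
* Methods with unmet preconditions (Egger/median/lasso need 3 instruments,
  penalized IVW needs 2) are marked failed inside `runAnalysis()` with the
  reason, while the remaining methods proceed — with only two total-protein
  instruments, IVW still runs.
* Files are plain delimited text with a header (tab or comma, sniffed);
  column names are remapped via `columnMap`, missing values are empty or
  `NA`.  Simulation configs are YAML.
* `runAnalysis()` is deterministic given files and seed, and
  `writeReport()` output is byte-stable, so reports can be diffed.

## Validation problem sizes

The shipped test suite validates parameter recovery with 200 two-sample
replicates at n = 20,000 per cohort (mean bias per estimator), IVW coverage
under the null with 500 replicates, planted-invalid-instrument detection by
MR-Lasso with 100 replicates, estimator-vs-oracle equivalences on random
small instances (weighted regression, brute-force median scan, closed-form
two-stratum Q), and the bundled instrument sets against their published
estimates at rounded-input tolerances (±0.005 for IVW/median/Egger betas and
heterogeneity p-values; ±0.03 for penalized IVW, which is the quantity most
sensitive to third-decimal rounding of the inputs).

## Limitations

Estimates inherit every instrumental-variable caveat: exclusion-restriction
violations beyond what Egger/lasso model, winner's curse in instrument
discovery, and sample overlap between exposure and outcome GWAS.  With two
instruments only IVW (and Cochran's Q) are available.  Stratified MR here
compares published stratum-level estimates; it does not re-derive
stratum-specific instrument effects.  The SE recovered from a printed CI is
only as precise as the printed decimals.
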