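---
title: "Modelling the post-mortem interval from vitreous humour metabolite profiles"
author: "pmivh authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the post-mortem interval from vitreous humour metabolite profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmivh)
```

## The problem

Estimating the post-mortem interval (PMI) — the time elapsed since death —
is a core task of forensic pathology. Vitreous humour (VH), the gel filling
the eye, is a biofluid of choice for post-mortem chemistry: it is
anatomically protected, degrades slowly, and its composition drifts in a
time-dependent way. The classical marker is the vitreous potassium
concentration, which rises roughly linearly after death. Proton NMR
metabolomics offers a multivariate alternative: a panel of ~50 quantified
metabolites whose concentrations rise or fall with PMI.

`pmivh` implements a complete chemometric pipeline for this setting, for
PMI windows of roughly 6–86 h and wide, strongly collinear predictor
blocks (more metabolites than training samples). It has two modelling
heads:

1. **An ordinal classifier** that predicts which PMI interval a sample
   belongs to (by default A: < 24 h, B: 24–48 h closed, C: > 48 h).
2. **A bounded regression** that predicts PMI in hours while guaranteeing
   non-negative predictions.

Both are built on a shared latent-variable core (PLS), validated by
repeated cross-validation and randomisation tests, and interpreted through
selectivity ratios.

## The latent-variable core

Because metabolite concentrations are strongly correlated and the
predictor block is wider than the sample count, ordinary regression is
ill-posed; projection to latent structures (PLS) is the standard
chemometric answer. `fit_pls2()` implements PLS2 with NIPALS deflation:
components are extracted one at a time, each maximising covariance between
a predictor score and the (deflated) response. Score vectors are mutually
orthogonal; with a single response and as many components as the predictor
rank, the fit coincides with ordinary least squares (a property the test
suite checks against `lm.fit`).

**Post-transformation.** For interpretation and for the ordinal pipeline,
the fitted A-dimensional score space is rotated (`post_transform()`) so
that a *single* predictive component $t_p$ carries all covariance with the
response, while the remaining $A-1$ components are response-orthogonal
(zero sample correlation). The rotation is orthogonal in score space, with
first axis $g \propto T^\top y$; fitted and predicted responses are
exactly invariant because they are the projection of $y$ onto the score
span either way. Any rotation with these properties is equivalent for
every downstream quantity we compute; this one is the simplest.

**Selectivity ratio.** For each metabolite $j$,
$\mathrm{SR}_j = \mathrm{ESS}_j / \mathrm{RSS}_j$: the variance of the
autoscaled metabolite explained by projection onto the $t_p$ direction,
over its residual variance. Values are signed by the Pearson correlation
of the metabolite with the response, and relevance is declared above the
critical value of an F distribution with $(N-2, N-3)$ degrees of freedom
at level $\alpha$ (default 0.05). This threshold form is a documented
convention, not a derived exactness result; a feature exactly collinear
with $t_p$ reports an infinite ratio, a zero-variance feature reports
`NA`.

## The ordinal head

PMI intervals are ordered, but with $n < p$ and collinear predictors,
ordered-logit models are not applicable. `fit_ordinal()` uses a three-step
construction:

1. **PLS2-C**: PLS on one column-centred dummy column per interval
   (`A1` components, default 3). Column-per-class coding keeps the classes
   symmetric.
2. **Post-transformed PLS on ranks**: the PLS2-C scores are regressed on
   the interval ranks (1, 2, 3) with `A2` components (default 2) and
   post-transformed, yielding one latent variable that encodes the
   ordering.
3. **Gaussian naive Bayes** on that latent variable: class-conditional
   means and variances with empirical priors turn the continuous latent
   value into an interval, with posterior probabilities. Ties break toward
   the lower rank; class variances are floored at $10^{-8}$ of the total
   latent variance to keep densities defined.

Interval boundary convention: the middle interval is closed
(a PMI of exactly 24 h or 48 h is B); this matters only for exact
boundary values. Component numbers are chosen by `tune_ordinal()`
minimising a cross-validated cost; the default cost is the mean absolute
rank error, which penalises skipping an interval twice as much as
stepping into an adjacent one. A plain misclassification rate is
available as an option.

## The bounded regression head

PMI is positive, and its relation to the metabolome is mildly non-linear.
`fit_bounded()` wraps PLS in a logit link: the training PMI range
$[y_{\min}, y_{\max}]$ is mapped affinely onto $[\varepsilon_1,
\varepsilon_2] \subset\, ]0,1[$, logit-transformed, and the resulting
unbounded response is modelled by PLS2 on the log-transformed, autoscaled
metabolite block. Predictions come back through the logistic function and
the inverse affine map.

Two readings of the back-map are possible: an exact inverse anchored on
the training range, or a map through the origin making $\varepsilon_1$ a
pure lower bound. We anchor on the training range (the exact inverse) and
clip negative back-images at zero; the upper limit $L$ — the back-image of
the logistic asymptote 1 — is reported with the model. Predictions
therefore always lie in $[0, L]$. With $\varepsilon_1, \varepsilon_2$
close to 0.5 the composite map is locally linear and the model reduces to
a plain PLS regression (verified to within 2% of the response range in
the tests); moving the pair toward 0 or 1 introduces controlled
non-linearity, compressing errors at the near end of the range.

$\varepsilon_1$, $\varepsilon_2$ and the component count are chosen by
`tune_bounded()`: exhaustive grid search maximising the mean
cross-validated $Q^2$, computed on the PMI scale with every
preprocessing step (scaling, map anchors) refitted inside each training
fold. Ties break toward fewer components, then toward the mildest
non-linearity. The default grids span
$\varepsilon_1 \in \{0.005, \dots, 0.45\}$,
$\varepsilon_2 \in \{\dots, 0.9\}$ (filtered to
$\varepsilon_2 > \varepsilon_1$), $A \in 1..5$.

**Potassium as a covariate.** Potassium can be appended as a single
power-transformed column $[K^+]^\gamma$, autoscaled after the power, with
$\gamma$ tuned on the same grid (default candidates 1–5). The validation
module also provides the complementary analyses: a univariate linear
potassium model with full metrics, and `residual_response_model()`, which
regresses potassium on the metabolites by PLS and asks whether the
*unexplained* potassium variance still carries PMI information (with
permutation p-values; a residual variance below $10^{-8}$ of the
potassium variance is reported as degenerate rather than modelled).

## Validation machinery

* `repeated_kfold()` — repeated stratified N-fold cross-validation
  (default 5 folds; regression folds stratify on response tertiles so
  every fold covers the PMI range). $Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$
  with TSS about the training-fold means, averaged over repeats. The
  estimator is a self-contained fit/predict recipe, so nothing fitted on
  the full data ever touches a held-out fold; a dedicated test plants a
  leaky variant and checks the honest version stays at $Q^2 \le 0$ on
  null data.
* `randomisation_test()` — permutes the response, recomputes a statistic
  (cross-validated $Q^2$ for regression, negative CV cost for the ordinal
  model), and reports the add-one p-value
  $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\mathrm{perm}} + 1)$, so
  the smallest attainable p is $1/(n_{\mathrm{perm}}+1)$.
* `rmse_by_interval()` — test errors split by true-PMI interval; the
  pooled RMSE recombines exactly by the law of total squares.
* `detect_outliers()` — PCA-based screening: Hotelling $T^2$ on the
  retained scores with the F-distribution limit, and the Q residual with
  the Jackson–Mudholkar limit. On clean Gaussian data both flag rates
  converge to $\alpha$.
* `fit_pca()` — exploration with $R^2$ from singular values and $Q^2$ by
  element-wise deletion cross-validation (7 diagonal deletion groups,
  EM-style rank-A re-imputation). This is a standard chemometrics
  construction; it is not intended to reproduce any particular commercial
  implementation bit for bit.

## Spectral preprocessing

For workflows starting from 1D spectra rather than quantified
metabolites, `bucket_spectra()` integrates each spectrum over fixed-width
ppm buckets (default 0.80–9.00 ppm at 0.02 ppm, i.e. 410 buckets) by the
trapezoidal rule on the native axis — exact for the piecewise-linear
interpolant, which makes bucketing a linear operator. Buckets
intersecting exclusion intervals are dropped *before* integration and
normalisation; the default water-exclusion window 4.5–5.2 ppm is an
assumption (instrument- and processing-dependent) and is a plain
parameter. `normalize_constant_sum()` scales each spectrum to a constant
total of 100. Scaling transforms (`mean_center`, `autoscale`,
`log_autoscale` with natural log) are fitted on training data only and
reused on new data.

## What the synthetic generator emulates

No public dataset accompanies this kind of study, so `generate_cohort()`
draws cohorts with the statistical structure the models assume:

* PMI uniform over 6–86 h, 71 samples, 52 named metabolites;
* log-concentration of metabolite $j$ =
  $\text{baseline}_j + s_j \cdot (\text{PMI} + \eta) + \text{factor noise}
  + \text{independent noise}$, so concentrations are log-normal and
  strictly positive;
* ten metabolites rising with PMI (alanine, glycine, glutamate,
  threonine, creatine, choline, succinate, hypoxanthine, taurine,
  ethanolamine) and three falling (glucose, 3-hydroxybutyrate, pyruvate),
  default slopes $\pm 0.02$ log-units/h;
* $\eta \sim N(0, 4.5^2\,\text{h}^2)$ is a per-animal "metabolic clock"
  offset: individual decomposition-rate variability shifts all trending
  metabolites coherently. This term is the dominant, irreducible floor on
  PMI recovery and is also the main source of inter-metabolite
  correlation, alongside rank-3 generic factor noise (scale 0.06) and
  independent noise (sd 0.15);
* potassium linear in the latent time, interpolating 7.6 mM at 6 h and
  39.2 mM at 84 h (slope ≈ 0.405 mM/h), Gaussian noise sd 5.8 mM,
  truncated at 0.1 mM. Together with the shared clock term this puts the
  univariate potassium–PMI $R^2$ near 0.58 — potassium is a usable but
  clearly weaker predictor than the metabolome, as in real vitreous
  humour cohorts.

With these defaults the closed-form oracle error — the Cramér–Rao bound
$1/\sqrt{s^\top \Sigma^{-1} s}$, available as `oracle_rmse()` — is
≈ 5 h, so a well-tuned model should reach a test RMSE within a factor
~1.5 of that. The noise split between the coherent clock term and
independent noise was set analytically from this bound, not fitted to any
model output.

A null cohort (`generate_null_cohort()`) keeps every marginal
distribution but drives the metabolites and potassium from a latent time
drawn independently of the reported PMI; it calibrates the randomisation
test. `generate_spectra()` renders a cohort as synthetic Lorentzian-peak
spectra (peak positions are synthetic, not literature chemical shifts) to
exercise the bucketing path.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: non-linear saturation of individual metabolite
trajectories, bacterial decomposition signatures at long PMI,
measurement batch effects, peak overlap and baseline artefacts in real
spectra, and any deviation from log-normal marginals. Results on
synthetic cohorts demonstrate correctness of the machinery, not field
performance.

## Numerical choices and degenerate inputs

* NIPALS stops with an error when a requested component exceeds the
  predictor rank; an identically-zero response yields zero regression
  coefficients (components fall back to principal directions).
* Sign convention: each weight vector's largest-magnitude element is
  positive, making scores reproducible across runs.
* The bounded map rejects $\varepsilon_2 - \varepsilon_1 < 10^{-6}$
  (slope overflow) and inputs whose affine image leaves $]0,1[$.
* Naive Bayes class-variance floor: $10^{-8}$ of the total latent
  variance; posterior rows that underflow entirely fall back to the
  nearest class mean.
* The Q-residual limit degenerates to a small positive tolerance
  ($10^{-9}$ of total variance) when the retained components reconstruct
  the data exactly.
* Zero-variance features: an error under autoscaling (with the offending
  index named), an `NA` in selectivity-ratio profiles.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full study design
(71 samples, 52 metabolites, 47/24 split) with moderately sized search
grids and cross-validation repeat counts (typically 5-point ε grids,
1–5 repeats, 199 permutations), chosen so the complete suite runs in a
few minutes on one core while every statistical claim keeps its designed
power. Heavier settings (20 repeats, 999 permutations, the full default
ε grid) are a flag away in `cv_spec()`, `randomisation_test()` and
`tune_bounded()`.

## Known limitations

* The SR relevance threshold and the PCA cross-validation scheme are
  conventions; alternative thresholds (e.g. permutation-based) can move
  individual metabolites across the relevance line.
* The ordinal head assumes a single dominant monotone latent trend; with
  several independent time-related processes the one-predictive-component
  construction would under-use the data.
* `L`, the upper prediction bound, depends on the tuned
  $(\varepsilon_1, \varepsilon_2)$ and can be far above the training
  range; it is a guarantee of finiteness, not a calibrated upper
  prediction limit.
* All validation here is internal or synthetic; applying the pipeline to
  real casework requires external validation on an independent cohort.
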