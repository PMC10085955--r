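# pmivh — post-mortem interval estimation from vitreous humour metabolite profiles

`pmivh` is an R package for chemometric estimation of the post-mortem
interval (PMI, hours since death) from ¹H NMR metabolite profiles of
vitreous humour, the setting in which forensic laboratories traditionally
rely on the vitreous potassium concentration. It targets the hard regime
of these studies: a few dozen samples, ~50 strongly collinear metabolite
concentrations, and a response that is positive and mildly non-linear in
the metabolome.

## What it implements

All modelling is built on projection to latent structures (PLS, NIPALS):

* **Ordinal interval classifier** — PMI intervals (A: < 24 h, B: 24–48 h,
  C: > 48 h) predicted by a three-step construction: PLS2 for
  classification on dummy-coded intervals → post-transformed PLS of the
  scores on the interval ranks (one predictive latent variable +
  response-orthogonal remainder) → Gaussian naive Bayes on the latent
  variable.
* **Bounded regression** — PMI mapped affinely onto
  [ε₁, ε₂] ⊂ ]0,1[, logit-transformed, modelled by PLS2 on the
  log-autoscaled metabolites, and back-transformed through the logistic
  function, so predictions are always in [0, L]. ε₁, ε₂, the component
  count and (optionally) a potassium power γ for a combined
  metabolites + [K⁺]^γ model are tuned by repeated cross-validation.
* **Selectivity ratio** — per-metabolite relevance on the predictive
  component, signed by the correlation with PMI, thresholded by an
  F(N−2, N−3) critical value.
* **Validation** — repeated stratified k-fold CV (Q², RMSECV),
  randomisation tests with add-one p-values, interval-wise RMSEP,
  PCA-based outlier screening (Hotelling T², Q residual with the
  Jackson–Mudholkar limit), univariate potassium model, and the
  potassium-residual analysis (is the potassium variance unexplained by
  the metabolites still related to PMI?).
* **Preprocessing** — spectral bucketing (trapezoidal, 0.02 ppm default,
  water-region exclusion), constant-sum-100 normalisation, mean
  centring / autoscaling / log-autoscaling fitted on training data only.
* **Synthetic cohorts** — `generate_cohort()` emulates an ovine vitreous
  humour study (71 samples, PMI 6–86 h, 52 metabolites with 13 planted
  monotone trends, potassium rising ≈ 0.405 mM/h, between-animal
  "metabolic clock" noise), with a closed-form oracle error
  (`oracle_rmse()`, ≈ 5 h at the defaults) and a PMI-independent null
  variant for calibrating the randomisation test. See the methods
  vignette (`vignettes/pmi-vitreous-metabolomics.Rmd`) for the model and
  its limits.

## Worked example

```r
library(pmivh)

cfg    <- cohort_config(seed = 1)          # 71 samples, 52 metabolites
cohort <- generate_cohort(cfg)
split  <- split_stratified(cohort, n_train = 47, strata_breaks = c(24, 48))
X_tr   <- metab_matrix(split$train);  y_tr <- split$train$pmi_h
X_te   <- metab_matrix(split$test);   y_te <- split$test$pmi_h

# ordinal interval classifier (3 PLS2-C components, 2 ptPLS2 components)
om <- fit_ordinal(X_tr, assign_levels(y_tr), A1 = 3, A2 = 2)
confusion(assign_levels(y_te), predict_levels(om, X_te)$labels)
#>     predicted
#> true A B C
#>    A 4 2 0
#>    B 0 7 1
#>    C 0 1 9
#> accuracy = 0.833, contiguity of errors = 1.00

# bounded regression at a fixed reference configuration
bm <- fit_bounded(X_tr, y_tr, eps1 = 0.02, eps2 = 0.10, A = 3)
bm
#> Bounded PLS model: 3 components, eps1 = 0.02, eps2 = 0.1, L = 971.6 h
#> R2 = 0.956, RMSEC = 4.78 h
sqrt(mean((y_te - predict_pmi(bm, X_te))^2))   # test RMSEP, hours
#> [1] 9.17664
oracle_rmse(cfg)                               # best achievable, hours
#> [1] 5.007867
```

The confusion table shows the held-out interval assignments — all errors
fall in adjacent intervals, as expected when the underlying process is a
continuous monotone drift. The bounded model's test error (≈ 9 h over an
80-h range, at this fixed untuned configuration) sits within a factor two
of the cohort's oracle error (≈ 5 h), the information limit set by the
generator's between-animal variability; tuning ε₁, ε₂ and the component
count by cross-validation (`tune_bounded()`) typically tightens the
median test error to within 1.5× the oracle.

`run_pipeline(pipeline_config(cohort, "out/"))` runs the whole study
(outlier screen, PCA, both model heads, potassium analyses, combined
model) and writes CSV/JSON reports; `inst/scripts/run_pipeline.R` wraps
it for the shell.

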