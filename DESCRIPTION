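Package: pmivh
Title: Post-Mortem Interval Estimation from Vitreous Humour Metabolite Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric modelling of the post-mortem interval (PMI) from
    1H NMR vitreous humour metabolite profiles. Provides an ordinal PLS
    classifier (PLS2 for classification, post-transformed PLS on level
    ranks, Gaussian naive Bayes on the predictive latent variable), a
    bounded logit-mapped PLS regression guaranteeing positive PMI
    predictions (optionally augmented with a power-transformed potassium
    covariate), selectivity-ratio variable relevance, NMR spectral
    bucketing and normalisation, PCA-based outlier screening, and the
    validation machinery (repeated stratified cross-validation,
    randomisation tests, interval-wise prediction errors). A synthetic
    cohort generator emulating an ovine vitreous humour study makes every
    stage testable without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
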