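test_that("cohort generation is deterministic and strictly positive", {
  cfg <- small_cfg(seed = 7)
  t1 <- generate_cohort(cfg)
  t2 <- generate_cohort(cfg)
  expect_identical(t1, t2)
  for (s in 1:10) {
    tab <- generate_cohort(small_cfg(n = 25, seed = s))
    expect_gt(min(metab_matrix(tab)), 0)
    expect_gt(min(tab$k_mM), 0)
  }
})

test_that("noise-free cohorts are monotone in PMI and zero-effect ones flat", {
  tab <- generate_cohort(noiseless_cfg())
  ord <- order(tab$pmi_h)
  conc <- metab_matrix(tab)
  for (j in 1:3) expect_true(all(diff(conc[ord, j]) > 0))
  expect_true(all(diff(conc[ord, ncol(conc)]) < 0))
  flat <- cohort_config(n_samples = 10, n_metabolites = 5,
                        metabolite_names = sprintf("m%d", 1:5),
                        increasing_set = integer(0),
                        decreasing_set = integer(0),
                        effect_sizes = rep(0, 5),
                        noise_rank = 0, factor_scale = 0, diag_scale = 0)
  conc <- metab_matrix(generate_cohort(flat))
  expect_lt(max(apply(conc, 2, sd)), 1e-12)
})

test_that("default potassium trajectory matches the reported range", {
  cfg <- cohort_config()
  expect_equal(cfg$k_intercept + 6 * cfg$k_slope, 7.6, tolerance = 1e-12)
  expect_equal(cfg$k_intercept + 84 * cfg$k_slope, 39.2, tolerance = 1e-12)
  expect_equal(cfg$k_slope, 0.405, tolerance = 1e-3)
})

test_that("config validation rejects contradictory settings", {
  expect_error(cohort_config(n_samples = 0), "positive")
  expect_error(small_cfg(increasing_set = 1:3, decreasing_set = 3),
               "disjoint")
  expect_error(cohort_config(pmi_range = c(10, 5)), "pmi_range")
})

test_that("null cohorts decouple PMI from metabolites and potassium", {
  cfg <- small_cfg(n = 2000, p = 10, seed = 3)
  tab <- generate_null_cohort(cfg)
  conc <- metab_matrix(tab)
  lim <- 3 / sqrt(nrow(tab))
  cors <- apply(conc, 2, function(x) cor(tab$pmi_h, x))
  expect_true(all(abs(cors) < lim))
  expect_lt(abs(cor(tab$pmi_h, tab$k_mM)), lim)
  expect_identical(generate_null_cohort(cfg), generate_null_cohort(cfg))
})

test_that("oracle RMSE of the default cohort sits near five hours", {
  v <- vapply(1:10, function(s) oracle_rmse(cohort_config(seed = s)),
              numeric(1))
  expect_true(all(v > 4 & v < 6))
  expect_identical(oracle_rmse(small_cfg(effect_sizes = rep(0, 20),
                                         increasing_set = integer(0),
                                         decreasing_set = integer(0))),
                   Inf)
})

test_that("stratified split reproduces the 47/24 design", {
  tab <- generate_cohort(cohort_config(seed = 2))
  sp <- split_stratified(tab, 47, c(24, 48), seed = 5)
  expect_equal(nrow(sp$train), 47)
  expect_equal(nrow(sp$test), 24)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), tab$sample_id)
  # per-stratum training proportions match the overall ratio within rounding
  lev <- ordinal_levels(c(24, 48))
  for (l in lev$labels) {
    n_l <- sum(assign_levels(tab$pmi_h, lev) == l)
    n_tr <- sum(assign_levels(sp$train$pmi_h, lev) == l)
    expect_lt(abs(n_tr - n_l * 47 / 71), 1)
  }
  expect_identical(split_stratified(tab, 47, seed = 5)$train$sample_id,
                   sp$train$sample_id)
  expect_equal(nrow(split_stratified(tab, 70)$test), 1)
  expect_error(split_stratified(tab, 0), "n_train")
  expect_error(split_stratified(tab, 47, c(100, 200)), "stratum")
})

test_that("synthetic spectra are linear in concentration", {
  tab <- generate_cohort(noiseless_cfg(n = 3, p = 2))
  lib <- data.frame(metabolite = "m01", ppm = 2, intensity = 1)
  sp <- generate_spectra(tab, lib, noise_sd = 0)
  bm <- bucket_spectra(sp, exclusions = list())
  conc <- metab_matrix(tab)
  # single peak, zero noise: bucket integral proportional to concentration
  j <- which.min(abs(bm$centers - 2))
  ratio <- bm$values[, j] / conc[, "m01"]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  # doubling a sample's concentrations doubles its bucket integrals
  lib <- data.frame(metabolite = c("m01", "m02"), ppm = c(2, 7),
                    intensity = 1)
  bm <- bucket_spectra(generate_spectra(tab, lib, noise_sd = 0),
                       exclusions = list())
  tab2 <- tab
  tab2[, attr(tab, "metabolites")] <- conc * 2
  sp2 <- generate_spectra(tab2, lib, noise_sd = 0)
  bm2 <- bucket_spectra(sp2, exclusions = list())
  expect_equal(bm2$values, bm$values * 2, tolerance = 1e-10)
  # zero concentrations give a flat noise-only spectrum
  tab0 <- tab
  tab0[, attr(tab, "metabolites")] <- 1e-300
  sp0 <- generate_spectra(tab0, lib, noise_sd = 0)
  expect_lt(max(abs(sp0$intensities)), 1e-290)
  expect_error(generate_spectra(tab, data.frame(metabolite = "m01",
                                                ppm = 12, intensity = 1)),
               "region")
})

test_that("cohort CSV round trip preserves the table", {
  tab <- generate_cohort(small_cfg(n = 8, p = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, path)
  back <- read_cohort(path)
  expect_equal(metab_matrix(back), metab_matrix(tab), tolerance = 1e-12)
  expect_equal(back$pmi_h, tab$pmi_h, tolerance = 1e-12)
})
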