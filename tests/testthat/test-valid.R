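test_that("repeated k-fold is deterministic and exact on perfect data", {
  set.seed(1)
  X <- matrix(rnorm(60), 30, 2)
  y <- drop(X %*% c(2, -1)) + 5
  cv <- cv_spec(n_folds = 5, n_repeats = 3, seed = 11)
  r1 <- repeated_kfold(pmivh:::.ols_estimator(), X, y, cv)
  expect_gt(r1$Q2, 1 - 1e-6)
  expect_lt(r1$RMSECV, 1e-6)
  r2 <- repeated_kfold(pmivh:::.ols_estimator(), X, y, cv)
  expect_identical(r1$folds, r2$folds)
  expect_error(repeated_kfold(pmivh:::.ols_estimator(), X, y,
                              cv_spec(n_folds = 40)), "fold count")
})

test_that("cross-validated Q2 of pure noise is non-positive", {
  q2 <- vapply(1:5, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(50 * 4), 50, 4)
    y <- rnorm(50)
    repeated_kfold(pmivh:::.ols_estimator(), X, y,
                   cv_spec(n_repeats = 3, seed = seed))$Q2
  }, numeric(1))
  expect_lte(median(q2), 0)
})

test_that("in-fold refitting protects against selection leakage", {
  honest <- leaked <- numeric(5)
  pick_best <- function(X, y) which.max(abs(cor(X, y)))
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 50), 40, 50)
    y <- rnorm(40)
    cv <- cv_spec(n_folds = 5, n_repeats = 2, seed = seed)
    honest_est <- list(
      fit = function(Xt, yt) {
        j <- pick_best(Xt, yt)  # selection refitted per fold
        list(j = j, fit = lm.fit(cbind(1, Xt[, j]), yt))
      },
      predict = function(m, Xt) {
        drop(cbind(1, Xt[, m$j]) %*% m$fit$coefficients)
      })
    j_all <- pick_best(X, y)  # selection peeks at the full data
    leaked_est <- list(
      fit = function(Xt, yt) lm.fit(cbind(1, Xt[, j_all]), yt),
      predict = function(m, Xt) {
        drop(cbind(1, Xt[, j_all]) %*% m$coefficients)
      })
    honest[seed] <- repeated_kfold(honest_est, X, y, cv)$Q2
    leaked[seed] <- repeated_kfold(leaked_est, X, y, cv)$Q2
  }
  expect_lte(median(honest), 0)
  expect_gt(median(leaked), median(honest))
})

test_that("randomisation test honours the add-one rule", {
  set.seed(2)
  x <- rnorm(30)
  y <- 3 * x + rnorm(30, sd = 0.1)  # signal dominates every permutation
  stat <- function(X1, y1) abs(cor(X1[, 1], y1))
  res <- randomisation_test(stat, matrix(x), y, n_perm = 99, seed = 3)
  expect_equal(res$p_value, 1 / 100)
  expect_length(res$null, 99)
  expect_true(res$passed)
  expect_error(randomisation_test(stat, matrix(x), y, n_perm = 0), "19")
  expect_error(randomisation_test(stat, matrix(x), rep(1, 30),
                                  n_perm = 99), "constant")
})

test_that("interval RMSEs partition correctly and recombine", {
  expect_equal(unname(rmse_by_interval(c(10, 30, 60), c(10, 30, 60))),
               c(0, 0, 0), ignore_attr = TRUE)
  r <- rmse_by_interval(c(10, 30, 60), c(15, 30, 60))
  expect_equal(unname(r[1]), 5)
  set.seed(4)
  y <- runif(100, 0, 90)
  p <- y + rnorm(100, sd = 5)
  r <- rmse_by_interval(y, p)
  n <- attr(r, "n")
  pooled <- sqrt(sum(n * r^2, na.rm = TRUE) / sum(n))
  expect_equal(pooled, sqrt(mean((y - p)^2)), tolerance = 1e-10)
  # empty interval reported as missing
  r2 <- rmse_by_interval(c(10, 12), c(10, 12), breaks = c(24, 48))
  expect_true(all(is.na(r2[2:3])))
  expect_error(rmse_by_interval(1:3, 1:2), "length")
})

test_that("univariate linear metrics behave at the extremes", {
  x <- seq(1, 20)
  m <- fit_univariate_linear(x, 2 * x, cv_spec(n_repeats = 2))
  expect_equal(m$R2, 1, tolerance = 1e-10)
  expect_lt(m$RMSEC, 1e-10)
  set.seed(5)
  q2 <- vapply(1:5, function(s) {
    set.seed(s)
    fit_univariate_linear(rnorm(200), rnorm(200),
                          cv_spec(n_repeats = 2, seed = s))$Q2
  }, numeric(1))
  expect_lte(median(q2), 0)
  # duplicating the dataset leaves the coefficients unchanged
  set.seed(6)
  x <- rnorm(30)
  y <- 1 + 2 * x + rnorm(30)
  c1 <- fit_univariate_linear(x, y, cv_spec(n_repeats = 1))$coefficients
  c2 <- fit_univariate_linear(rep(x, 2), rep(y, 2),
                              cv_spec(n_repeats = 1))$coefficients
  expect_equal(c1, c2, tolerance = 1e-10)
  expect_error(fit_univariate_linear(rep(1, 10), 1:10), "constant")
})

test_that("potassium-residual analysis flags degenerate and null cases", {
  tab <- generate_cohort(small_cfg(n = 40, seed = 12))
  X <- metab_matrix(tab)
  cv <- cv_spec(n_repeats = 2, seed = 1)
  # potassium an exact linear function of two log-metabolites
  k_exact <- drop(2 * log(X[, 1]) - log(X[, 2])) + 10
  # full-rank PLS coincides with least squares, so the fit is exact
  res <- residual_response_model(X, k_exact, tab$pmi_h, A = ncol(X),
                                 cv = cv, n_perm = 49)
  expect_lt(res$residual_var_ratio, 1e-8)
  expect_false(res$reliable)
  expect_null(res$metrics)
  # potassium pure noise, independent of X and y
  set.seed(13)
  k_noise <- rexp(40) + 1
  res2 <- residual_response_model(X, k_noise, tab$pmi_h, A = 1, cv = cv,
                                  n_perm = 49)
  expect_lte(res2$metrics$Q2, 0.05)
  expect_false(res2$reliable)
  expect_error(residual_response_model(X, k_noise, tab$pmi_h, A = 0,
                                       cv = cv), "A must")
})

test_that("greedy refinement finds a planted predictor and stays monotone", {
  set.seed(14)
  n <- 40
  X <- cbind(matrix(rnorm(n * 6), n, 6), signal = NA)
  y <- runif(n, 0, 80)
  X[, 7] <- y / 2
  colnames(X) <- c(paste0("noise", 1:6), "signal")
  cv <- cv_spec(n_folds = 5, n_repeats = 1, seed = 2)
  rep <- predictor_subset_refinement(X, y, cv)
  expect_equal(rep$subset[1], "signal")
  expect_lt(rep$path$RMSECV[1], 1e-8)
  expect_true(all(diff(rep$path$RMSECV) <= 1e-12))
  # all-noise predictors: subset does not beat the full model materially
  set.seed(15)
  Xn <- matrix(rnorm(n * 5), n, 5)
  yte <- runif(20, 0, 80)
  Xte <- matrix(rnorm(20 * 5), 20, 5)
  rep2 <- predictor_subset_refinement(Xn, rnorm(n), cv,
                                      X_test = Xte, y_test = rnorm(20))
  expect_lt(abs(rep2$rmsep_subset - rep2$rmsep_full),
            2 * rep2$rmsep_full)
  expect_error(predictor_subset_refinement(Xn[, 1, drop = FALSE],
                                           rnorm(n), cv), "two predictors")
})
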