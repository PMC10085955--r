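test_that("single-predictor PLS recovers the least-squares slope", {
  set.seed(1)
  x <- rnorm(40)
  y <- 2.5 * x + rnorm(40)
  m <- fit_pls2(matrix(x), y, 1)
  slope_ols <- cov(x, y) / var(x)  # closed-form oracle
  pred <- predict_response(m, matrix(c(0, 1)))
  expect_equal(pred[2] - pred[1], slope_ols, tolerance = 1e-8)
})

test_that("full-rank single-response PLS equals OLS, exact fits are exact", {
  for (seed in 1:5) {
    inst <- random_instance(20, 8, seed)
    m <- fit_pls2(inst$X, inst$y, 8)
    ols <- lm.fit(cbind(1, inst$X), inst$y)
    expect_equal(drop(predict_response(m, inst$X)),
                 drop(cbind(1, inst$X) %*% ols$coefficients),
                 tolerance = 1e-6)
  }
  # y exactly in the column space: zero training residual
  set.seed(11)
  X <- matrix(rnorm(160), 20, 8)
  y <- drop(X %*% rnorm(8))
  m <- fit_pls2(X, y, 8)
  expect_lt(max(abs(drop(m$fitted) - y)), 1e-8)
})

test_that("degenerate responses and inputs are handled", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3)
  m <- fit_pls2(X, rep(0, 20), 2)
  expect_lt(max(abs(m$B)), 1e-12)
  expect_error(fit_pls2(X[1, , drop = FALSE], 1, 1), "2 samples")
  expect_error(fit_pls2(cbind(X, X), rnorm(20), 7), "rank")
})

test_that("PLS scores are orthogonal and predictions self-consistent", {
  set.seed(3)
  X <- matrix(rnorm(47 * 12), 47, 12)
  Y <- cbind(drop(X %*% rnorm(12)) + rnorm(47), rnorm(47))
  m <- fit_pls2(X, Y, 4)
  g <- crossprod(m$T)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
  expect_equal(predict_response(m, X), m$fitted, tolerance = 1e-10)
  # predicting at the column means returns the response means
  expect_equal(drop(predict_response(m, matrix(colMeans(X), 1))),
               colMeans(Y), tolerance = 1e-10)
  # duplicated rows get identical predictions
  two <- predict_response(m, X[c(5, 5), ])
  expect_identical(two[1, ], two[2, ])
})

test_that("PLS2-C dummy coding follows the class-symmetric contract", {
  set.seed(4)
  X <- matrix(rnorm(60 * 10), 60, 10)
  lab <- rep(c("A", "B", "C"), each = 20)
  m <- fit_pls2c(X, lab, 2)
  expect_equal(m$class_levels, c("A", "B", "C"))
  Y <- model.matrix(~ factor(lab) - 1)
  expect_equal(unname(colSums(Y)), rep(20, 3))
  # centred dummy block for 2 classes has rank 1
  Y2 <- scale(model.matrix(~ factor(rep(c("A", "B"), 10)) - 1),
              scale = FALSE)
  expect_equal(qr(Y2)$rank, 1)
  expect_error(fit_pls2c(X, rep("A", 60), 2), "two distinct")
  expect_error(fit_pls2c(X, c("B", rep("A", 59)), 2), "two samples")
})

test_that("separated Gaussian classes separate on the first PLS2-C score", {
  set.seed(5)
  n <- 60
  lab <- rep(c("A", "B", "C"), each = n / 3)
  shift <- (as.integer(factor(lab)) - 2) * 8
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 1] <- X[, 1] + shift
  m <- fit_pls2c(X, lab, 2, x_scaling = "mean_center")
  t1 <- m$T[, 1]
  expect_true(max(t1[lab == "A"]) < min(t1[lab == "B"]) ||
                min(t1[lab == "A"]) > max(t1[lab == "B"]))
  expect_true(max(t1[lab == "B"]) < min(t1[lab == "C"]) ||
                min(t1[lab == "B"]) > max(t1[lab == "C"]))
})

test_that("post-transformation isolates the response into one component", {
  set.seed(6)
  X <- matrix(rnorm(47 * 52), 47, 52)
  y <- drop(X %*% rnorm(52)) + rnorm(47)
  m <- fit_pls2(X, y, 3)
  ptm <- post_transform(m, y)
  # orthogonal scores carry no response correlation
  for (j in seq_len(ncol(ptm$T_o))) {
    expect_lt(abs(cor(ptm$T_o[, j], y)), 1e-8)
  }
  # predictions invariant under the rotation
  expect_lt(max(abs(predict_ptpls(ptm, X) - drop(m$fitted))), 1e-8)
  Xnew <- matrix(rnorm(10 * 52), 10, 52)
  expect_lt(max(abs(predict_ptpls(ptm, Xnew) -
                      drop(predict_response(m, Xnew)))), 1e-8)
  # A = 1: the predictive score is the single score up to sign
  m1 <- fit_pls2(X, y, 1)
  p1 <- post_transform(m1, y)
  expect_equal(abs(p1$t_p), abs(drop(m1$T)), tolerance = 1e-10)
  expect_error(post_transform(m, rep(1, 47)), "constant")
})

test_that("selectivity ratio marks collinear and orthogonal features", {
  set.seed(7)
  n <- 40
  t_p <- rnorm(n)
  ortho <- residuals(lm(rnorm(n) ~ t_p))
  X <- cbind(col_lin = 3 * t_p,                      # exactly collinear
             col_ort = ortho,                        # exactly orthogonal
             matrix(rnorm(n * 5), n, 5))
  y <- t_p + rnorm(n, sd = 0.1)
  sr <- selectivity_ratio(t_p, X, y)
  expect_true(is.infinite(sr$sr[1]))
  expect_true(sr$relevant[1])
  expect_lt(sr$sr[2], 1e-10)
  expect_false(sr$relevant[2])
  # zero-variance feature reported as missing, not an error
  sr0 <- selectivity_ratio(t_p, cbind(X, const = 1), y)
  expect_true(is.na(sr0$sr[8]))
})

test_that("selectivity ratio is invariant to positive feature rescaling", {
  set.seed(8)
  tab <- generate_cohort(small_cfg(n = 50))
  X <- metab_matrix(tab)
  y <- tab$pmi_h
  m <- fit_pls2(X, y, 3, x_scaling = "log_autoscale")
  ptm <- post_transform(m, y)
  sr1 <- selectivity_ratio(ptm, X, y)
  X2 <- X
  X2[, 3] <- X2[, 3] * 17
  sr2 <- selectivity_ratio(ptm, X2, y)
  expect_equal(sr1$sr[3], sr2$sr[3], tolerance = 1e-10)
})

test_that("selectivity ratio recovers planted informative metabolites", {
  hits <- integer(0)
  false_flags <- integer(0)
  for (seed in 1:5) {
    cfg <- small_cfg(n = 50, seed = seed)
    tab <- generate_cohort(cfg)
    X <- metab_matrix(tab)
    y <- tab$pmi_h
    m <- fit_pls2(X, y, 3, x_scaling = "log_autoscale")
    sr <- selectivity_ratio(post_transform(m, y), X, y)
    informative <- c(cfg$increasing_set, cfg$decreasing_set)
    hits <- c(hits, sum(sr$relevant[informative]))
    false_flags <- c(false_flags, sum(sr$relevant[-informative]))
    # signs track the planted trend directions
    expect_true(all(sr$signed_sr[cfg$increasing_set] > 0))
    expect_true(all(sr$signed_sr[cfg$decreasing_set] < 0))
  }
  expect_gte(median(hits), 5 * 0.9)
  expect_lte(median(false_flags), 3)
})

test_that("PCA explains rank-2 data exactly and is sign-invariant", {
  set.seed(9)
  X <- matrix(rnorm(60), 30, 2) %*% matrix(rnorm(16), 2, 8)
  pca <- fit_pca(X, 2)
  expect_equal(pca$R2[2], 1, tolerance = 1e-10)
  expect_true(all(diff(pca$R2) >= -1e-12))
  recon1 <- pca$scores %*% t(pca$loadings)
  recon2 <- (pca$scores %*% diag(c(-1, 1))) %*%
    t(pca$loadings %*% diag(c(-1, 1)))
  expect_equal(recon1, recon2, tolerance = 1e-12)
  expect_error(fit_pca(X, 5), "rank")
})

test_that("PCA Q2 is negative for isotropic noise and below R2", {
  q2 <- r2 <- numeric(5)
  for (seed in 1:5) {
    set.seed(seed)
    X <- scale(matrix(rnorm(40 * 10), 40, 10))
    p <- fit_pca(X, 2)
    q2[seed] <- p$Q2[2]
    r2[seed] <- p$R2[2]
  }
  expect_lte(median(q2), 0)
  expect_true(all(q2 <= r2))
})
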