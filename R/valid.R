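#' Cross-validation specification
#'
#' @param n_folds Number of folds (>= 2, default 5).
#' @param n_repeats Number of repeats (default 20).
#' @param stratify One of "pmi-strata" (tertiles of the response, default
#'   for regression), "class", or "none".
#' @param seed Integer seed making fold assignments reproducible.
#' @return Object of class `cv_spec`.
#' @export
cv_spec <- function(n_folds = 5, n_repeats = 20,
                    stratify = c("pmi-strata", "class", "none"),
                    seed = 1L) {
  stratify <- match.arg(stratify)
  if (n_folds < 2) stop("n_folds must be at least 2")
  if (n_repeats < 1) stop("n_repeats must be at least 1")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratify = stratify, seed = as.integer(seed)),
            class = "cv_spec")
}

# Fold assignments for all repeats: list of integer vectors (1..n_folds).
# Stratified assignment shuffles within each stratum and deals folds
# round-robin, so every fold is non-empty and strata stay balanced.
.make_fold_sets <- function(n, cv, strata = NULL) {
  if (n < cv$n_folds) stop("fold count exceeds the number of samples")
  set.seed(cv$seed)
  if (is.null(strata)) strata <- rep(1L, n)
  strata <- as.factor(strata)
  lapply(seq_len(cv$n_repeats), function(r) {
    assign <- integer(n)
    offset <- 0L
    for (s in levels(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- ((offset + seq_along(idx) - 1L) %% cv$n_folds) + 1L
      offset <- offset + length(idx)
    }
    assign
  })
}

# Response strata for regression CV: tertiles of y.
.pmi_strata <- function(y) {
  qs <- stats::quantile(y, c(1 / 3, 2 / 3), names = FALSE)
  cut(y, breaks = c(-Inf, qs, Inf), labels = FALSE)
}

#' Repeated N-fold cross-validation of an estimator recipe
#'
#' The estimator is a self-contained fit/predict pair (all preprocessing
#' refitted inside each training fold, so nothing leaks into the held-out
#' fold). Per repeat, out-of-fold predictions give
#' `Q2 = 1 - PRESS / TSS` with the total sum of squares taken about the
#' training-fold means; `Q2` and `RMSECV` are averaged over repeats.
#'
#' @param estimator List with functions `fit(X, y)` and
#'   `predict(model, X)`.
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param cv A [cv_spec()].
#' @param strata Optional explicit stratification factor; otherwise
#'   derived from `cv$stratify`.
#' @return Object of class `cv_result`: `Q2`, `RMSECV`, per-repeat values
#'   `q2_repeats`, `rmsecv_repeats`, and the fold assignments.
#' @export
repeated_kfold <- function(estimator, X, y, cv = cv_spec(), strata = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("X and y sizes differ")
  if (is.null(strata)) {
    strata <- switch(cv$stratify,
                     "pmi-strata" = .pmi_strata(y),
                     "class" = y,
                     "none" = NULL)
  }
  folds <- .make_fold_sets(n, cv, strata = strata)
  q2r <- numeric(cv$n_repeats)
  rmser <- numeric(cv$n_repeats)
  for (r in seq_len(cv$n_repeats)) {
    assign <- folds[[r]]
    press <- 0
    tss <- 0
    for (f in seq_len(cv$n_folds)) {
      te <- assign == f
      m <- estimator$fit(X[!te, , drop = FALSE], y[!te])
      yhat <- estimator$predict(m, X[te, , drop = FALSE])
      press <- press + sum((y[te] - yhat)^2)
      tss <- tss + sum((y[te] - mean(y[!te]))^2)
    }
    q2r[r] <- 1 - press / tss
    rmser[r] <- sqrt(press / n)
  }
  structure(list(Q2 = mean(q2r), RMSECV = mean(rmser),
                 q2_repeats = q2r, rmsecv_repeats = rmser, folds = folds),
            class = "cv_result")
}

#' Randomisation (permutation) test of a model statistic
#'
#' Recomputes the statistic under `n_perm` random permutations of the
#' response and reports the add-one permutation p-value
#' `(1 + #{null >= observed}) / (n_perm + 1)`; the minimum attainable p is
#' therefore `1 / (n_perm + 1)`. Typical statistics: Q2 for regression
#' models, negative CV cost for the ordinal classifier.
#'
#' @param statistic Function `statistic(X, y)` returning a scalar for
#'   which larger means better.
#' @param X Predictor matrix.
#' @param y Response vector (non-constant).
#' @param n_perm Number of permutations (>= 19).
#' @param alpha Significance level (default 0.05).
#' @param seed Seed for the permutations.
#' @return Object of class `perm_result`: `observed`, `null` (length
#'   `n_perm`), `p_value`, `passed`.
#' @export
randomisation_test <- function(statistic, X, y, n_perm, alpha = 0.05,
                               seed = 1L) {
  y <- as.numeric(y)
  if (stats::sd(y) == 0) stop("y must not be constant")
  if (n_perm < 19) stop("n_perm must be at least 19")
  observed <- statistic(X, y)
  set.seed(as.integer(seed))
  perms <- replicate(n_perm, sample.int(length(y)), simplify = FALSE)
  null <- vapply(perms, function(pm) statistic(X, y[pm]), numeric(1))
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null = null, p_value = p,
                 passed = p <= alpha, alpha = alpha, n_perm = n_perm),
            class = "perm_result")
}

#' Interval-wise root-mean-square prediction error
#'
#' Partitions samples by their true PMI into the ordered intervals defined
#' by `breaks` (same boundary convention as [assign_levels()]) and reports
#' the RMSE per interval; empty intervals give `NA`. The pooled RMSE obeys
#' the law of total squares over the intervals.
#'
#' @param y_true,y_pred Equal-length PMI vectors (hours).
#' @param breaks Sorted break points (default c(24, 48)).
#' @return Named numeric vector of per-interval RMSEs with an `n`
#'   attribute (samples per interval).
#' @export
rmse_by_interval <- function(y_true, y_pred, breaks = c(24, 48)) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  lev <- ordinal_levels(breaks = breaks)
  grp <- assign_levels(y_true, lev)
  out <- vapply(lev$labels, function(l) {
    i <- grp == l
    if (!any(i)) return(NA_real_)
    sqrt(mean((y_true[i] - y_pred[i])^2))
  }, numeric(1))
  attr(out, "n") <- vapply(lev$labels, function(l) sum(grp == l),
                           integer(1))
  out
}

# Ordinary least squares estimator recipe (single predictor or matrix).
.ols_estimator <- function() {
  list(
    fit = function(X, y) {
      stats::lm.fit(cbind(1, as.matrix(X)), y)
    },
    predict = function(model, X) {
      drop(cbind(1, as.matrix(X)) %*% model$coefficients)
    })
}

#' Univariate linear regression with full validation metrics
#'
#' Ordinary least squares of the response on a single predictor (the
#' potassium-versus-PMI analysis), with R2/RMSEC in calibration, Q2/RMSECV
#' by repeated cross-validation, and RMSEP on an optional test split.
#'
#' @param x Predictor vector (non-constant).
#' @param y Response vector (hours).
#' @param cv A [cv_spec()].
#' @param x_test,y_test Optional test split for RMSEP.
#' @return Object of class `fit_metrics`: `R2`, `Q2`, `RMSEC`, `RMSECV`,
#'   `RMSEP` (NA without a test split), `coefficients`.
#' @export
fit_univariate_linear <- function(x, y, cv = cv_spec(), x_test = NULL,
                                  y_test = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (stats::sd(x) == 0) stop("x must not be constant")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  rmsec <- sqrt(mean(res^2))
  cvres <- repeated_kfold(.ols_estimator(), matrix(x, ncol = 1), y, cv)
  rmsep <- NA_real_
  if (!is.null(x_test)) {
    pred <- stats::predict(fit, data.frame(x = as.numeric(x_test)))
    rmsep <- sqrt(mean((as.numeric(y_test) - pred)^2))
  }
  structure(list(R2 = r2, Q2 = cvres$Q2, RMSEC = rmsec,
                 RMSECV = cvres$RMSECV, RMSEP = rmsep,
                 coefficients = stats::coef(fit), cv = cvres),
            class = "fit_metrics")
}

#' PMI on the variance of potassium unexplained by the metabolites
#'
#' Fits a PLS2 model of potassium on the metabolite block, takes the
#' training residual (the potassium variance the metabolites do not
#' explain), and models PMI on that residual by univariate linear
#' regression with cross-validated Q2 and permutation p-values for both R2
#' and Q2. When the residual variance is numerically zero (potassium an
#' exact function of the metabolites) the downstream model is degenerate
#' and reported unreliable.
#'
#' @param X Metabolite matrix, raw scale.
#' @param k Potassium vector (mM, positive).
#' @param y PMI hours.
#' @param A PLS components for the potassium model (>= 1).
#' @param cv A [cv_spec()].
#' @param n_perm Permutations for the p-values (default 199).
#' @param alpha Significance level.
#' @param x_scaling Metabolite scaling (default "log_autoscale").
#' @return List with `k_model` (`pls_model`), `residual`,
#'   `residual_var_ratio` (var(residual)/var(k)), `metrics`
#'   (`fit_metrics` for PMI on the residual, or NULL when degenerate),
#'   `p_R2`, `p_Q2`, `reliable`.
#' @export
residual_response_model <- function(X, k, y, A, cv = cv_spec(),
                                    n_perm = 199, alpha = 0.05,
                                    x_scaling = "log_autoscale") {
  if (A < 1) stop("A must be at least 1")
  if (any(k <= 0)) stop("potassium values must be strictly positive")
  k_model <- fit_pls2(as.matrix(X), k, A, x_scaling = x_scaling,
                      y_scaling = "mean_center")
  r <- k - drop(k_model$fitted)
  ratio <- stats::var(r) / stats::var(k)
  if (ratio < 1e-8) {
    return(list(k_model = k_model, residual = r,
                residual_var_ratio = ratio, metrics = NULL,
                p_R2 = NA_real_, p_Q2 = NA_real_, reliable = FALSE))
  }
  metrics <- fit_univariate_linear(r, y, cv)
  rmat <- matrix(r, ncol = 1)
  stat_r2 <- function(X1, y1) {
    f <- stats::lm.fit(cbind(1, X1), y1)
    1 - sum(f$residuals^2) / sum((y1 - mean(y1))^2)
  }
  cv1 <- cv
  cv1$n_repeats <- min(cv$n_repeats, 3L)  # permutation inner CV kept light
  stat_q2 <- function(X1, y1) {
    repeated_kfold(.ols_estimator(), X1, y1, cv1)$Q2
  }
  p_r2 <- randomisation_test(stat_r2, rmat, y, n_perm, alpha,
                             seed = cv$seed)$p_value
  p_q2 <- randomisation_test(stat_q2, rmat, y, n_perm, alpha,
                             seed = cv$seed + 1L)$p_value
  reliable <- metrics$Q2 > 0 && p_q2 <= alpha
  list(k_model = k_model, residual = r, residual_var_ratio = ratio,
       metrics = metrics, p_R2 = p_r2, p_Q2 = p_q2, reliable = reliable)
}

#' Greedy forward predictor-subset refinement
#'
#' Grows a predictor subset greedily, at each step adding the predictor
#' that most reduces the cross-validated RMSE, stopping when no candidate
#' improves it. Reports the selection path (non-increasing RMSECV), the
#' test-set RMSEP of the subset model versus the full model, and the RMSEP
#' of each single selected predictor, mirroring the check that subset
#' gains are small while single predictors degrade sharply.
#'
#' @param X Predictor matrix (>= 2 columns).
#' @param y Response vector.
#' @param cv A [cv_spec()].
#' @param estimator Estimator recipe applied to column subsets (default
#'   ordinary least squares).
#' @param X_test,y_test Optional test split for the RMSEP comparisons.
#' @param max_size Cap on the subset size (default all predictors).
#' @return Object of class `subset_report`: `subset` (selected column
#'   names), `path` (data frame step/feature/RMSECV), `rmsep_subset`,
#'   `rmsep_full`, `rmsep_single` (named vector), `rmsecv_full`.
#' @export
predictor_subset_refinement <- function(X, y, cv = cv_spec(),
                                        estimator = .ols_estimator(),
                                        X_test = NULL, y_test = NULL,
                                        max_size = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least two predictors")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(max_size)) max_size <- ncol(X)
  cv_rmse <- function(cols) {
    repeated_kfold(estimator, X[, cols, drop = FALSE], y, cv)$RMSECV
  }
  selected <- integer(0)
  best_rmse <- Inf
  path <- data.frame(step = integer(0), feature = character(0),
                     RMSECV = numeric(0), stringsAsFactors = FALSE)
  repeat {
    if (length(selected) >= max_size) break
    cand <- setdiff(seq_len(ncol(X)), selected)
    scores <- vapply(cand, function(j) cv_rmse(c(selected, j)), numeric(1))
    j_best <- cand[which.min(scores)]
    if (min(scores) >= best_rmse) break
    best_rmse <- min(scores)
    selected <- c(selected, j_best)
    path <- rbind(path, data.frame(step = length(selected),
                                   feature = colnames(X)[j_best],
                                   RMSECV = best_rmse,
                                   stringsAsFactors = FALSE))
  }
  rmsecv_full <- cv_rmse(seq_len(ncol(X)))
  rmsep_subset <- rmsep_full <- NA_real_
  rmsep_single <- stats::setNames(rep(NA_real_, length(selected)),
                                  colnames(X)[selected])
  if (!is.null(X_test)) {
    X_test <- as.matrix(X_test)
    test_rmse <- function(cols) {
      m <- estimator$fit(X[, cols, drop = FALSE], y)
      sqrt(mean((y_test - estimator$predict(
        m, X_test[, cols, drop = FALSE]))^2))
    }
    rmsep_subset <- test_rmse(selected)
    rmsep_full <- test_rmse(seq_len(ncol(X)))
    rmsep_single <- vapply(selected, test_rmse, numeric(1))
    names(rmsep_single) <- colnames(X)[selected]
  }
  structure(list(subset = colnames(X)[selected], path = path,
                 rmsecv_subset = best_rmse, rmsecv_full = rmsecv_full,
                 rmsep_subset = rmsep_subset, rmsep_full = rmsep_full,
                 rmsep_single = rmsep_single),
            class = "subset_report")
}
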