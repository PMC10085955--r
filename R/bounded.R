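#' Bounded logit map between PMI and the regression space
#'
#' `make_map` builds the affine map sending the training PMI range
#' `[min(y), max(y)]` onto `[eps1, eps2]` inside ]0,1[; the regression
#' response is the logit of that image. The inverse applies the logistic
#' function and the inverse affine map, then clips negative values to 0,
#' so back-transformed predictions always fall in `[0, L]` where `L`
#' (reported in the map) is the back-image of the logistic limit 1.
#'
#' @param y_train Training PMI vector in hours (non-constant, >= 0).
#' @param eps1,eps2 Map parameters, 0 < eps1 < eps2 < 1. Values close to
#'   0.5 give an almost linear model; values toward 0 or 1 introduce
#'   non-linearity.
#' @return Object of class `bounded_map` with `eps1`, `eps2`, `y_min`,
#'   `y_max`, `L`.
#' @export
make_map <- function(y_train, eps1, eps2) {
  y_train <- as.numeric(y_train)
  if (any(y_train < 0)) stop("PMI must be non-negative")
  y_min <- min(y_train)
  y_max <- max(y_train)
  if (y_max <= y_min) stop("y_train must not be constant")
  if (!(eps1 > 0 && eps2 < 1 && eps2 > eps1)) {
    stop("need 0 < eps1 < eps2 < 1")
  }
  if (eps2 - eps1 < 1e-6) stop("eps2 - eps1 too small (degenerate map)")
  L <- y_min + (1 - eps1) * (y_max - y_min) / (eps2 - eps1)
  structure(list(eps1 = eps1, eps2 = eps2, y_min = y_min, y_max = y_max,
                 L = L),
            class = "bounded_map")
}

#' @rdname make_map
#' @param map A `bounded_map`.
#' @param y PMI values whose affine image must lie in ]0,1[.
#' @return `map_forward`: logit-scale response values.
#' @export
map_forward <- function(map, y) {
  eps <- map$eps1 + (map$eps2 - map$eps1) * (y - map$y_min) /
    (map$y_max - map$y_min)
  if (any(eps <= 0 | eps >= 1)) {
    stop("affine image leaves ]0,1[; PMI outside the mappable range")
  }
  log(eps / (1 - eps))
}

#' @rdname make_map
#' @param z Logit-scale values (any real).
#' @return `map_inverse`: PMI in hours, clipped below at 0 (always in
#'   `[0, L]`).
#' @export
map_inverse <- function(map, z) {
  eps <- stats::plogis(z)
  y <- map$y_min + (eps - map$eps1) * (map$y_max - map$y_min) /
    (map$eps2 - map$eps1)
  pmax(y, 0)
}

#' Fit the bounded (logit-mapped) PLS regression for PMI
#'
#' PMI is mapped through [make_map()] / [map_forward()] to an unbounded
#' logit response, which is modelled by PLS2 on the scaled predictor
#' block. Predictions come back through the logistic inverse, guaranteeing
#' non-negative PMI. Optionally a potassium covariate is appended as an
#' autoscaled power transform `k^gamma`.
#'
#' @param X Metabolite concentration matrix, raw (positive) scale.
#' @param y PMI hours.
#' @param eps1,eps2 Map parameters (see [make_map()]).
#' @param A Number of PLS components.
#' @param gamma Power for the potassium covariate (required with `k`).
#' @param k Optional potassium vector (mM, positive).
#' @param x_scaling Scaling of the metabolite block (default
#'   "log_autoscale").
#' @return Object of class `bounded_model`: `map`, `pls`, `gamma`,
#'   `k_scaling` (or NULL), `R2` and `RMSEC` on the original PMI scale,
#'   and training `fitted` values.
#' @export
fit_bounded <- function(X, y, eps1, eps2, A, gamma = NULL, k = NULL,
                        x_scaling = "log_autoscale") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!is.null(k)) {
    if (is.null(gamma)) stop("gamma is required when k is supplied")
    if (any(k <= 0)) stop("potassium values must be strictly positive")
  }
  map <- make_map(y, eps1, eps2)
  z <- map_forward(map, y)
  sx <- fit_scaling(X, x_scaling)
  pred <- apply_scaling(X, sx)
  k_scaling <- NULL
  if (!is.null(k)) {
    kp <- matrix(power_transform(k, gamma), ncol = 1,
                 dimnames = list(NULL, "k_gamma"))
    k_scaling <- fit_scaling(kp, "autoscale")
    pred <- cbind(pred, apply_scaling(kp, k_scaling))
  }
  pls <- fit_pls2(pred, z, A, x_scaling = "mean_center",
                  y_scaling = "mean_center")
  fitted <- pmin(map_inverse(map, drop(pls$fitted)), map$L)
  rmsec <- sqrt(mean((y - fitted)^2))
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  structure(list(map = map, pls = pls, gamma = if (is.null(k)) 1 else gamma,
                 x_scaling = sx, k_scaling = k_scaling,
                 predictor_names = colnames(pred), A = A,
                 fitted = fitted, R2 = r2, RMSEC = rmsec, y_train = y),
            class = "bounded_model")
}

#' Predict PMI from a bounded model
#'
#' @param model A `bounded_model`.
#' @param Xnew New metabolite matrix (raw scale; feature count must match).
#' @param knew Potassium vector; required iff the model was fitted with
#'   one.
#' @return Predicted PMI hours, all in `[0, L]`.
#' @export
predict_pmi <- function(model, Xnew, knew = NULL) {
  Xnew <- as.matrix(Xnew)
  pred <- apply_scaling(Xnew, model$x_scaling)
  if (!is.null(model$k_scaling)) {
    if (is.null(knew)) stop("model was fitted with potassium; supply knew")
    kp <- matrix(power_transform(knew, model$gamma), ncol = 1)
    pred <- cbind(pred, apply_scaling(kp, model$k_scaling))
  } else if (!is.null(knew)) {
    stop("model was fitted without potassium")
  }
  # the inner PLS re-applies its own training-mean centring of the block
  z <- drop(predict_response(model$pls, pred))
  pmin(map_inverse(model$map, z), model$map$L)
}

#' Grid search for the bounded model by repeated cross-validation
#'
#' Exhaustive search over (eps1, eps2, A[, gamma]) maximising the mean
#' cross-validated Q2 on the PMI scale, with all preprocessing (scaling,
#' map anchors) refitted inside each training fold. Ties break toward
#' fewer components, then toward the (eps1, eps2) pair closest to
#' (0.5, 0.5) (mildest non-linearity).
#'
#' @param X Metabolite matrix, raw scale.
#' @param y PMI hours.
#' @param eps1_grid,eps2_grid Candidate map parameters; pairs with
#'   eps2 <= eps1 are dropped.
#' @param a_grid Candidate component numbers.
#' @param gamma_grid Candidate powers for potassium (ignored without `k`).
#' @param k Optional potassium vector.
#' @param cv A [cv_spec()]; regression folds stratify on PMI tertiles by
#'   default.
#' @param x_scaling Metabolite scaling.
#' @return List with `model` (refit on all data at the winning
#'   configuration), `best` (winning parameter row with Q2 and RMSECV),
#'   and `results` (full grid with CV metrics).
#' @export
tune_bounded <- function(X, y,
                         eps1_grid = c(0.005, 0.01, 0.015, 0.02, 0.05,
                                       0.1, 0.2, 0.3, 0.45),
                         eps2_grid = c(0.005, 0.01, 0.015, 0.02, 0.05,
                                       0.1, 0.2, 0.3, 0.45, 0.5, 0.7, 0.9),
                         a_grid = 1:5, gamma_grid = 1, k = NULL,
                         cv = cv_spec(), x_scaling = "log_autoscale") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(k)) gamma_grid <- 1
  grid <- expand.grid(eps1 = eps1_grid, eps2 = eps2_grid, A = a_grid,
                      gamma = gamma_grid)
  grid <- grid[grid$eps2 > grid$eps1 + 1e-6, , drop = FALSE]
  if (nrow(grid) == 0) stop("empty grid after the eps2 > eps1 constraint")
  grid$Q2 <- NA_real_
  grid$RMSECV <- NA_real_
  for (i in seq_len(nrow(grid))) {
    est <- bounded_estimator(grid$eps1[i], grid$eps2[i], grid$A[i],
                             gamma = grid$gamma[i], x_scaling = x_scaling)
    res <- tryCatch(
      repeated_kfold(est, if (is.null(k)) X else cbind(X, .k = k), y, cv),
      error = function(e) NULL)
    if (!is.null(res)) {
      grid$Q2[i] <- res$Q2
      grid$RMSECV[i] <- res$RMSECV
    }
  }
  ok <- which(!is.na(grid$Q2))
  if (length(ok) == 0) stop("no grid point could be cross-validated")
  d_mid <- sqrt((grid$eps1 - 0.5)^2 + (grid$eps2 - 0.5)^2)
  ord <- ok[order(-grid$Q2[ok], grid$A[ok], d_mid[ok])]
  best <- grid[ord[1], ]
  model <- fit_bounded(X, y, best$eps1, best$eps2, best$A,
                       gamma = if (is.null(k)) NULL else best$gamma,
                       k = k, x_scaling = x_scaling)
  list(model = model, best = best, results = grid)
}

#' Estimator recipe for a bounded model (for CV and permutation machinery)
#'
#' Packages [fit_bounded()] / [predict_pmi()] as a self-contained
#' fit/predict pair usable by [repeated_kfold()] and
#' [randomisation_test()]. When the model uses potassium, append it to `X`
#' as a final column named `.k`; the recipe splits it off inside each
#' fold, so no preprocessing leaks across folds.
#'
#' @param eps1,eps2,A,gamma,x_scaling Passed to [fit_bounded()].
#' @return List with `fit(X, y)` and `predict(model, X)` functions.
#' @export
bounded_estimator <- function(eps1, eps2, A, gamma = 1,
                              x_scaling = "log_autoscale") {
  split_k <- function(X) {
    X <- as.matrix(X)
    if (".k" %in% colnames(X)) {
      list(X = X[, colnames(X) != ".k", drop = FALSE], k = X[, ".k"])
    } else {
      list(X = X, k = NULL)
    }
  }
  list(
    fit = function(X, y) {
      s <- split_k(X)
      fit_bounded(s$X, y, eps1, eps2, A,
                  gamma = if (is.null(s$k)) NULL else gamma, k = s$k,
                  x_scaling = x_scaling)
    },
    predict = function(model, X) {
      s <- split_k(X)
      predict_pmi(model, s$X, knew = s$k)
    })
}
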