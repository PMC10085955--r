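#' Fit a PLS2 regression model (NIPALS)
#'
#' Projection to latent structures with NIPALS deflation. Scaling is fitted
#' on the supplied data and stored, so prediction on new data reuses the
#' training parameters. Score vectors are mutually orthogonal; with a single
#' response and `A` equal to the predictor rank the fit coincides with
#' ordinary least squares.
#'
#' @param X Predictor matrix (samples x features), raw scale.
#' @param Y Response matrix or vector, raw scale.
#' @param A Number of latent components (1 <= A <= rank(X)).
#' @param x_scaling,y_scaling Scaling method for each block (see
#'   [fit_scaling()]).
#' @param tol,max_iter NIPALS convergence tolerance and iteration cap
#'   (multi-response case only; single responses are solved directly).
#' @return Object of class `pls_model` with weights `W`, loadings `P`,
#'   scores `T`, response loadings `C`, corrected weights `Wstar`,
#'   regression coefficients `B` (scaled space), the two `scaling_params`,
#'   fitted values on the original response scale, and `R2`.
#' @export
fit_pls2 <- function(X, Y, A, x_scaling = "mean_center",
                     y_scaling = "mean_center", tol = 1e-10, max_iter = 200) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 2) stop("at least 2 samples are required")
  if (nrow(Y) != n) stop("X and Y must have the same number of samples")
  A <- as.integer(A)
  if (A < 1) stop("A must be at least 1")
  sx <- fit_scaling(X, x_scaling)
  sy <- fit_scaling(Y, y_scaling)
  Xd <- apply_scaling(X, sx)
  Yd <- apply_scaling(Y, sy)
  p <- ncol(Xd)
  q <- ncol(Yd)
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  C <- matrix(0, q, A)
  x_tot <- sum(Xd^2)
  y_tot <- sum(Yd^2)
  for (a in seq_len(A)) {
    if (sum(Yd^2) <= 1e-24 * max(y_tot, 1)) {
      # response (residual) numerically zero: carry on with principal
      # directions of the predictor residual so scores stay defined while
      # the response loadings, and hence B, are zero
      w <- svd(Xd, nu = 0, nv = 1)$v[, 1]
    } else if (q == 1L) {
      w <- drop(crossprod(Xd, Yd))
    } else {
      u <- Yd[, which.max(colSums(Yd^2))]
      w <- drop(crossprod(Xd, u))
      for (it in seq_len(max_iter)) {
        w <- w / sqrt(sum(w^2))
        t_vec <- drop(Xd %*% w)
        cvec <- drop(crossprod(Yd, t_vec)) / sum(t_vec^2)
        u_new <- drop(Yd %*% cvec) / sum(cvec^2)
        if (sqrt(sum((u_new - u)^2)) < tol * sqrt(sum(u_new^2) + 1e-300)) {
          u <- u_new
          break
        }
        u <- u_new
        w <- drop(crossprod(Xd, u))
      }
      w <- drop(crossprod(Xd, u))
    }
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn < 1e-12 * sqrt(x_tot + 1e-300)) {
      stop("A exceeds the rank of the predictor block (component ", a, ")")
    }
    w <- w / wn
    # sign convention: largest-magnitude weight element positive
    if (w[which.max(abs(w))] < 0) w <- -w
    t_vec <- drop(Xd %*% w)
    tt <- sum(t_vec^2)
    if (tt < 1e-12 * x_tot / p) {
      stop("A exceeds the rank of the predictor block (component ", a, ")")
    }
    pvec <- drop(crossprod(Xd, t_vec)) / tt
    cvec <- drop(crossprod(Yd, t_vec)) / tt
    W[, a] <- w
    P[, a] <- pvec
    Tm[, a] <- t_vec
    C[, a] <- cvec
    Xd <- Xd - tcrossprod(t_vec, pvec)
    Yd <- Yd - tcrossprod(t_vec, cvec)
  }
  Wstar <- W %*% solve(crossprod(P, W))
  B <- Wstar %*% t(C)
  Ys <- apply_scaling(Y, sy)
  fitted_s <- Tm %*% t(C)
  fitted <- inverse_scaling(fitted_s, sy)
  ss_res <- sum((Ys - fitted_s)^2)
  ss_tot <- sum(Ys^2)
  structure(list(A = A, W = W, P = P, T = Tm, C = C, Wstar = Wstar, B = B,
                 x_scaling = sx, y_scaling = sy, n = n,
                 fitted = fitted, R2 = 1 - ss_res / ss_tot),
            class = "pls_model")
}

#' Project new samples onto the score space of a PLS model
#'
#' @param model A `pls_model`.
#' @param Xnew New predictor matrix on the raw scale.
#' @return Matrix of scores (samples x A).
#' @export
project_scores <- function(model, Xnew) {
  Xs <- apply_scaling(as.matrix(Xnew), model$x_scaling)
  Xs %*% model$Wstar
}

#' Predict responses from a PLS model
#'
#' Applies the stored training scaling, the regression coefficients, and the
#' inverse response scaling.
#'
#' @param model A `pls_model`.
#' @param Xnew New predictor matrix, raw scale; feature count must match.
#' @return Predicted response matrix on the original scale.
#' @export
predict_response <- function(model, Xnew) {
  Xs <- apply_scaling(as.matrix(Xnew), model$x_scaling)
  inverse_scaling(Xs %*% model$B, model$y_scaling)
}

#' Fit a PLS2 classification model (PLS2-C)
#'
#' Encodes the class labels as one column-centred dummy column per class and
#' fits a PLS2 model; the score components feed the ordinal pipeline.
#'
#' @param X Predictor matrix, raw scale.
#' @param labels Factor (or coercible) class labels; at least two classes,
#'   each with at least two samples.
#' @param A Number of components.
#' @param x_scaling Predictor scaling (default "autoscale").
#' @return A `pls_model` that is also of class `pls2c_model`, with
#'   `class_levels` recorded.
#' @export
fit_pls2c <- function(X, labels, A, x_scaling = "autoscale") {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (length(counts) < 2) stop("at least two distinct classes are required")
  if (any(counts < 2)) stop("every class needs at least two samples")
  Y <- stats::model.matrix(~ labels - 1)
  colnames(Y) <- levels(labels)
  m <- fit_pls2(X, Y, A, x_scaling = x_scaling, y_scaling = "mean_center")
  m$class_levels <- levels(labels)
  class(m) <- c("pls2c_model", class(m))
  m
}

#' Post-transformation of a PLS model
#'
#' Rotates the A-dimensional score space so that a single predictive
#' component `t_p` carries all covariance with the response and the
#' remaining A-1 components are response-orthogonal (zero sample
#' correlation with `y`). Fitted and predicted responses are unchanged by
#' the rotation.
#'
#' @param model A fitted `pls_model`.
#' @param y Numeric response vector (e.g. level ranks); non-constant.
#' @return Object of class `ptpls_model`: the base model, rotation matrix
#'   `G` (first column is the predictive direction `g`), predictive score
#'   `t_p`, orthogonal scores `T_o`, predictive weight vector in predictor
#'   space, least-squares coefficients on the rotated scores, and
#'   `predictive_R2` (response variance explained by `t_p` alone).
#' @export
post_transform <- function(model, y) {
  stopifnot(inherits(model, "pls_model"))
  y <- as.numeric(y)
  if (length(y) != model$n) stop("y length must match the fitted samples")
  if (stats::sd(y) == 0) stop("y must not be constant")
  yc <- y - mean(y)
  Tm <- model$T
  A <- model$A
  g_raw <- drop(crossprod(Tm, yc))
  gn <- sqrt(sum(g_raw^2))
  if (gn < 1e-12) stop("response has no covariance with the score space")
  g <- g_raw / gn
  G <- qr.Q(qr(matrix(g, ncol = 1)), complete = TRUE)
  if (sum(G[, 1] * g) < 0) G <- -G
  Trot <- Tm %*% G
  t_p <- Trot[, 1]
  T_o <- Trot[, -1, drop = FALSE]
  coef <- drop(solve(crossprod(Trot), crossprod(Trot, yc)))
  pred_r2 <- drop(crossprod(t_p, yc))^2 / (sum(t_p^2) * sum(yc^2))
  structure(list(base = model, G = G, g = g, t_p = t_p, T_o = T_o,
                 coef = coef, intercept = mean(y),
                 predictive_weight = drop(model$Wstar %*% g),
                 predictive_R2 = pred_r2),
            class = "ptpls_model")
}

#' Predict the response modelled by a post-transformed PLS model
#'
#' @param ptm A `ptpls_model`.
#' @param Xnew New predictor matrix on the raw scale of the base model.
#' @return Numeric vector of predictions (identical to refitting the base
#'   model response on the rotated score space).
#' @export
predict_ptpls <- function(ptm, Xnew) {
  Tn <- project_scores(ptm$base, Xnew)
  drop(Tn %*% ptm$G %*% ptm$coef) + ptm$intercept
}

# Predictive scores of new samples (internal).
.ptpls_scores <- function(ptm, Xnew) {
  drop(project_scores(ptm$base, Xnew) %*% ptm$g)
}

#' Selectivity ratio on the predictive component
#'
#' For every feature, the ratio of the sum of squares explained by
#' projection onto the predictive score direction to the residual sum of
#' squares, computed on the autoscaled feature block. Values are signed by
#' the Pearson correlation of the raw feature with the response; relevance
#' is declared when the (unsigned) ratio exceeds the critical value of an
#' F distribution with (N-2, N-3) degrees of freedom at level `alpha`.
#'
#' Features exactly collinear with the predictive score get an infinite
#' ratio (flagged relevant); zero-variance features get `NA`.
#'
#' @param ptm A `ptpls_model`, or directly a numeric predictive score
#'   vector.
#' @param X Feature matrix the scores were derived from (raw scale).
#' @param y Response vector used for the correlation signs.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `sr_profile`: data frame with columns `feature`,
#'   `sr`, `signed_sr`, `relevant`, plus attributes `threshold` and
#'   `alpha`.
#' @export
selectivity_ratio <- function(ptm, X, y, alpha = 0.05) {
  t_p <- if (inherits(ptm, "ptpls_model")) ptm$t_p else as.numeric(ptm)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(t_p) != n) stop("score length must match the sample count")
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  ok <- sds > 0
  Xs <- sweep(X, 2, ctr, `-`)
  Xs[, ok] <- sweep(Xs[, ok, drop = FALSE], 2, sds[ok], `/`)
  u <- t_p - mean(t_p)
  u <- u / sqrt(sum(u^2))
  proj <- drop(crossprod(Xs, u))          # per-feature loading on t_p
  ess <- proj^2
  tot <- colSums(Xs^2)
  rss <- pmax(tot - ess, 0)
  sr <- ifelse(ok, ifelse(rss < 1e-12 * pmax(ess, 1e-300), Inf, ess / rss),
               NA_real_)
  sgn <- vapply(seq_len(ncol(X)), function(j) {
    if (!ok[j]) return(0)
    s <- stats::cor(X[, j], y)
    if (is.na(s) || s == 0) 0 else sign(s)
  }, numeric(1))
  threshold <- stats::qf(1 - alpha, n - 2, n - 3)
  out <- data.frame(feature = colnames(X) %||% paste0("x", seq_len(ncol(X))),
                    sr = sr, signed_sr = sr * sgn,
                    relevant = !is.na(sr) & sr > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("sr_profile", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal component analysis with cross-validated Q2
#'
#' PCA by singular value decomposition of the (already scaled) data matrix.
#' `R2` is the cumulative fraction of total variance from the singular
#' values; `Q2` is estimated by element-wise deletion cross-validation:
#' matrix cells are assigned to deletion groups in a diagonal pattern, each
#' group is deleted in turn and re-imputed by an EM-style iterated SVD of
#' the given rank, and PRESS is accumulated on the deleted cells.
#'
#' @param X Scaled data matrix.
#' @param A Number of components (<= rank).
#' @param n_groups Number of deletion groups (default 7).
#' @param max_iter,tol EM iteration controls.
#' @return Object of class `pca_model`: `loadings`, `scores`, cumulative
#'   `R2` and `Q2` vectors (length A), eigenvalues.
#' @export
fit_pca <- function(X, A, n_groups = 7, max_iter = 50, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  A <- as.integer(A)
  sv <- svd(X)
  if (A < 1 || A > sum(sv$d > 1e-10 * sv$d[1])) {
    stop("A exceeds the rank of the data")
  }
  r2 <- cumsum(sv$d^2)[seq_len(A)] / sum(sv$d^2)
  grp <- (outer(seq_len(n), seq_len(p), `+`) %% n_groups) + 1L
  ss_tot <- sum(X^2)
  q2 <- numeric(A)
  for (a in seq_len(A)) {
    press <- 0
    for (g in seq_len(n_groups)) {
      miss <- grp == g
      Xw <- X
      Xw[miss] <- 0
      recon <- Xw
      for (it in seq_len(max_iter)) {
        s <- svd(Xw, nu = a, nv = a)
        recon <- s$u %*% (s$d[seq_len(a)] * t(s$v))
        delta <- sqrt(mean((recon[miss] - Xw[miss])^2))
        Xw[miss] <- recon[miss]
        if (delta < tol) break
      }
      press <- press + sum((X[miss] - recon[miss])^2)
    }
    q2[a] <- 1 - press / ss_tot
  }
  structure(list(A = A, loadings = sv$v[, seq_len(A), drop = FALSE],
                 scores = sv$u[, seq_len(A), drop = FALSE] %*%
                   diag(sv$d[seq_len(A)], A),
                 eigenvalues = sv$d^2 / (n - 1), R2 = r2, Q2 = q2),
            class = "pca_model")
}
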