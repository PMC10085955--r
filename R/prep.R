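#' Bucket (bin) a set of 1D NMR spectra
#'
#' Segments the given spectral region into fixed-width ppm buckets and
#' integrates each sample's intensity over each bucket with the trapezoidal
#' rule on the native axis (exact for the piecewise-linear interpolant, so
#' bucketing is a linear operator on spectra). Buckets intersecting any
#' exclusion interval (e.g. the residual water resonance) are dropped before
#' integration.
#'
#' @param spectra A `spectrum_set` (list with `ppm`, `intensities`).
#' @param region ppm interval to bucket (default c(0.80, 9.00)).
#' @param width Bucket width in ppm (default 0.02).
#' @param exclusions List of ppm intervals to exclude (default: the
#'   water region 4.5-5.2 ppm; pass `list()` for none).
#' @return Object of class `bucket_matrix`: list with `values` (samples x
#'   buckets), `edges` (buckets x 2), `centers`, `width`,
#'   `excluded_regions`. Column names are bucket centers to 4 decimals.
#' @export
bucket_spectra <- function(spectra, region = c(0.80, 9.00), width = 0.02,
                           exclusions = list(c(4.5, 5.2))) {
  ppm <- spectra$ppm
  y <- spectra$intensities
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (ppm[1] > ppm[length(ppm)]) {  # accept descending axes
    ppm <- rev(ppm)
    y <- y[, rev(seq_along(ppm)), drop = FALSE]
  }
  if (width <= 0) stop("width must be positive")
  if (width > diff(region)) stop("width larger than region")
  if (region[1] < ppm[1] - 1e-9 || region[2] > ppm[length(ppm)] + 1e-9) {
    stop("region outside the spectral axis span")
  }
  n_buckets <- floor(diff(region) / width + 1e-9)
  edges_lo <- region[1] + width * (seq_len(n_buckets) - 1)
  edges_hi <- edges_lo + width
  keep <- rep(TRUE, n_buckets)
  for (ex in exclusions) {
    keep <- keep & !(edges_lo < ex[2] & edges_hi > ex[1])
  }
  # cumulative trapezoidal integral at grid nodes, per sample
  dx <- diff(ppm)
  seg <- (y[, -1, drop = FALSE] + y[, -ncol(y), drop = FALSE]) / 2 *
    rep(dx, each = nrow(y))
  cum <- cbind(0, t(apply(seg, 1, cumsum)))
  eval_cum <- function(at) {
    i <- findInterval(at, ppm, all.inside = TRUE)
    w <- at - ppm[i]
    f_at <- y[, i, drop = FALSE] +
      sweep(y[, i + 1, drop = FALSE] - y[, i, drop = FALSE], 2, w / dx[i], `*`)
    cum[, i, drop = FALSE] +
      sweep(y[, i, drop = FALSE] + f_at, 2, w / 2, `*`)
  }
  vals <- eval_cum(edges_hi) - eval_cum(edges_lo)
  vals <- vals[, keep, drop = FALSE]
  centers <- (edges_lo + edges_hi)[keep] / 2
  colnames(vals) <- sprintf("%.4f", centers)
  rownames(vals) <- rownames(spectra$intensities)
  structure(list(values = vals,
                 edges = cbind(lo = edges_lo[keep], hi = edges_hi[keep]),
                 centers = centers, width = width,
                 excluded_regions = exclusions),
            class = "bucket_matrix")
}

#' Constant-sum normalisation
#'
#' Scales every row (spectrum) so its bucket values sum to `total`
#' (default 100).
#'
#' @param x A `bucket_matrix` or a numeric matrix.
#' @param total Target row sum (default 100).
#' @return Same type as the input with rows rescaled.
#' @export
normalize_constant_sum <- function(x, total = 100) {
  m <- if (inherits(x, "bucket_matrix")) x$values else as.matrix(x)
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("every row must have a positive sum")
  m <- m * (total / rs)
  if (inherits(x, "bucket_matrix")) {
    x$values <- m
    x
  } else {
    m
  }
}

#' Fit / apply / invert feature scaling
#'
#' `fit_scaling` learns per-feature transforms from training data:
#' `mean_center` (subtract column means), `autoscale` (centre and divide by
#' the column standard deviation), or `log_autoscale` (natural log followed
#' by autoscaling). `apply_scaling` reuses the stored training parameters on
#' new data; `inverse_scaling` undoes the transform.
#'
#' @param X Numeric matrix (samples x features).
#' @param method One of "mean_center", "autoscale", "log_autoscale".
#' @return `fit_scaling`: an object of class `scaling_params`;
#'   `apply_scaling`/`inverse_scaling`: a transformed matrix.
#' @export
fit_scaling <- function(X, method = c("mean_center", "autoscale",
                                      "log_autoscale")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (method == "log_autoscale") {
    if (any(X <= 0)) stop("log_autoscale requires strictly positive values")
    X <- log(X)
  }
  ctr <- colMeans(X)
  if (method == "mean_center") {
    scl <- rep(1, ncol(X))
  } else {
    scl <- apply(X, 2, stats::sd)
    bad <- which(scl <= 0 | !is.finite(scl))
    if (length(bad)) {
      stop("zero-variance feature(s) under autoscaling: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(method = method, center = ctr, scale = scl),
            class = "scaling_params")
}

#' @rdname fit_scaling
#' @param params A `scaling_params` object from `fit_scaling`.
#' @export
apply_scaling <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$center)) stop("feature count mismatch")
  if (params$method == "log_autoscale") {
    if (any(X <= 0)) stop("log_autoscale requires strictly positive values")
    X <- log(X)
  }
  sweep(sweep(X, 2, params$center, `-`), 2, params$scale, `/`)
}

#' @rdname fit_scaling
#' @export
inverse_scaling <- function(X, params) {
  X <- as.matrix(X)
  out <- sweep(sweep(X, 2, params$scale, `*`), 2, params$center, `+`)
  if (params$method == "log_autoscale") out <- exp(out)
  out
}

#' Elementwise power transform
#'
#' `x^gamma` for strictly positive input; `gamma = 1` is the identity. Used
#' to include potassium as a power-transformed covariate.
#'
#' @param x Vector of positive reals.
#' @param gamma Positive power.
#' @return `x^gamma`.
#' @export
power_transform <- function(x, gamma) {
  if (any(x <= 0)) stop("power_transform requires strictly positive input")
  if (length(gamma) != 1 || gamma <= 0) stop("gamma must be a positive scalar")
  x^gamma
}

#' PCA-based multivariate outlier screening
#'
#' Fits a PCA with `n_components` to the (column-centred) data and computes,
#' per sample, the Hotelling T2 statistic on the retained scores and the
#' Q residual (squared off-model distance). Control limits at level `alpha`:
#' T2 via the Hotelling F-distribution form
#' `A(n-1)(n+1) / (n(n-A)) * F(1-alpha; A, n-A)`; Q via the
#' Jackson-Mudholkar approximation from the discarded eigenvalues.
#'
#' @param X Numeric matrix; centred internally.
#' @param n_components Number of retained components (< min(n, p)).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `outlier_report`: per-sample `t2`, `q`,
#'   limits `t2_limit`, `q_limit`, and logical `t2_flag`, `q_flag`.
#' @export
detect_outliers <- function(X, n_components, alpha = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  a <- as.integer(n_components)
  if (a < 1 || a >= min(n, p)) {
    stop("n_components must be in 1..(min(n, p) - 1)")
  }
  Xc <- sweep(X, 2, colMeans(X), `-`)
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1)
  if (ev[a] < 1e-12 * ev[1]) stop("n_components exceeds the data rank")
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  t2 <- rowSums(sweep(scores[, seq_len(a), drop = FALSE]^2, 2,
                      ev[seq_len(a)], `/`))
  recon <- scores[, seq_len(a), drop = FALSE] %*%
    t(sv$v[, seq_len(a), drop = FALSE])
  q <- rowSums((Xc - recon)^2)
  t2_limit <- a * (n - 1) * (n + 1) / (n * (n - a)) *
    stats::qf(1 - alpha, a, n - a)
  resid_ev <- ev[-seq_len(a)]
  resid_ev <- resid_ev[resid_ev > 0]
  if (length(resid_ev) == 0 || sum(resid_ev) < 1e-12 * sum(ev)) {
    # numerically exact reconstruction: only a true off-model departure
    # (relative to the retained variance) should ever flag
    q_limit <- 1e-9 * sum(ev)
  } else {
    th1 <- sum(resid_ev)
    th2 <- sum(resid_ev^2)
    th3 <- sum(resid_ev^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
    ca <- stats::qnorm(1 - alpha)
    q_limit <- th1 * (ca * sqrt(2 * th2 * h0^2) / th1 +
                        1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  }
  structure(list(t2 = t2, q = q, t2_limit = t2_limit, q_limit = q_limit,
                 t2_flag = t2 > t2_limit, q_flag = q > q_limit,
                 n_components = a, alpha = alpha),
            class = "outlier_report")
}
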