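#' Default metabolite panel
#'
#' Names for the simulated metabolite panel. The first thirteen are the
#' vitreous humour metabolites with a known PMI trend (ten rising, three
#' falling); the remainder are uninformative filler metabolites.
#'
#' @param n Total number of metabolites (at least 13 when the named panel is
#'   used; default 52).
#' @return Character vector of length `n`.
#' @export
default_metabolite_names <- function(n = 52) {
  up <- c("alanine", "glycine", "glutamate", "threonine", "creatine",
          "choline", "succinate", "hypoxanthine", "taurine", "ethanolamine")
  down <- c("glucose", "three_hydroxybutyrate", "pyruvate")
  named <- c(up, down)
  if (n < length(named)) {
    return(named[seq_len(n)])
  }
  c(named, sprintf("met_%02d", seq_len(n - length(named))))
}

#' Configuration of a synthetic vitreous humour cohort
#'
#' Defines the generative model for a synthetic cohort: PMI sampled uniformly
#' over `pmi_range`; log-concentration of metabolite j equal to
#' `baseline_j + slope_j * PMI + correlated noise`, where the noise is a
#' low-rank factor model plus a diagonal term; potassium rising linearly with
#' PMI with Gaussian noise, truncated below at 0.1 mM.
#'
#' Default slopes are +`effect_size_up` for the ten rising metabolites and
#' `effect_size_down` for the three falling ones (see
#' [default_metabolite_names()]); all other metabolites carry no PMI signal.
#' Default potassium intercept/slope interpolate 7.6 mM at 6 h and 39.2 mM at
#' 84 h, i.e. a slope of (39.2 - 7.6)/78 ~ 0.405 mM/h; the default noise
#' (5.8 mM, on top of the shared clock term) puts the univariate
#' potassium-PMI coefficient of determination near 0.58.
#'
#' @param n_samples Number of samples (default 71).
#' @param pmi_range Lower/upper PMI in hours; lower must be >= 0 (default
#'   c(6, 86)).
#' @param n_metabolites Number of metabolites (default 52).
#' @param metabolite_names Optional character vector of names.
#' @param increasing_set,decreasing_set Integer indices of metabolites rising
#'   resp. falling with PMI; must be disjoint. Defaults: the named panel.
#' @param effect_size_up,effect_size_down Slopes (log-concentration per hour)
#'   applied to the two sets when `effect_sizes` is not given.
#' @param effect_sizes Optional full per-metabolite slope vector; overrides
#'   the set-based defaults.
#' @param time_noise_sd Between-animal "metabolic clock" variability in
#'   hours: each animal's trending metabolites follow an effective time
#'   `PMI + eta`, `eta ~ N(0, time_noise_sd^2)`. This coherent noise is the
#'   dominant floor on how well PMI can be recovered, while each trending
#'   metabolite still shows a clear trend.
#' @param noise_rank Number of latent noise factors (default 3).
#' @param factor_scale Standard deviation scale of factor loadings.
#' @param diag_scale Standard deviation of the diagonal (independent) noise.
#' @param k_intercept,k_slope Potassium intercept (mM) and slope (mM/h).
#' @param k_noise_sd Potassium noise standard deviation (mM).
#' @param pmi_dependent If `FALSE`, metabolites and potassium are driven by a
#'   latent PMI independent of the reported one (null cohort with identical
#'   marginals).
#' @param seed Integer seed; the whole table is a deterministic function of
#'   the configuration.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [oracle_rmse()]
#' @export
cohort_config <- function(n_samples = 71,
                          pmi_range = c(6, 86),
                          n_metabolites = 52,
                          metabolite_names = NULL,
                          increasing_set = NULL,
                          decreasing_set = NULL,
                          effect_size_up = 0.02,
                          effect_size_down = -0.02,
                          effect_sizes = NULL,
                          time_noise_sd = 4.5,
                          noise_rank = 3,
                          factor_scale = 0.06,
                          diag_scale = 0.15,
                          k_intercept = 7.6 - 6 * (39.2 - 7.6) / 78,
                          k_slope = (39.2 - 7.6) / 78,
                          k_noise_sd = 5.8,
                          pmi_dependent = TRUE,
                          seed = 1L) {
  if (length(n_samples) != 1L || is.na(n_samples) || n_samples < 1) {
    stop("n_samples must be a positive count")
  }
  n_samples <- as.integer(n_samples)
  if (length(pmi_range) != 2L || pmi_range[1] < 0 || pmi_range[2] <= pmi_range[1]) {
    stop("pmi_range must satisfy 0 <= lower < upper")
  }
  n_metabolites <- as.integer(n_metabolites)
  if (n_metabolites < 1) stop("n_metabolites must be positive")
  if (is.null(metabolite_names)) {
    metabolite_names <- default_metabolite_names(n_metabolites)
  }
  if (length(metabolite_names) != n_metabolites) {
    stop("metabolite_names must have length n_metabolites")
  }
  if (is.null(increasing_set) || is.null(decreasing_set)) {
    up <- match(c("alanine", "glycine", "glutamate", "threonine", "creatine",
                  "choline", "succinate", "hypoxanthine", "taurine",
                  "ethanolamine"), metabolite_names)
    dn <- match(c("glucose", "three_hydroxybutyrate", "pyruvate"),
                metabolite_names)
    if (is.null(increasing_set)) increasing_set <- up[!is.na(up)]
    if (is.null(decreasing_set)) decreasing_set <- dn[!is.na(dn)]
  }
  increasing_set <- as.integer(increasing_set)
  decreasing_set <- as.integer(decreasing_set)
  if (length(intersect(increasing_set, decreasing_set)) > 0) {
    stop("increasing_set and decreasing_set must be disjoint")
  }
  if (any(c(increasing_set, decreasing_set) < 1) ||
      any(c(increasing_set, decreasing_set) > n_metabolites)) {
    stop("informative sets must index 1..n_metabolites")
  }
  if (is.null(effect_sizes)) {
    effect_sizes <- numeric(n_metabolites)
    effect_sizes[increasing_set] <- effect_size_up
    effect_sizes[decreasing_set] <- effect_size_down
  }
  if (length(effect_sizes) != n_metabolites) {
    stop("effect_sizes must have length n_metabolites")
  }
  if (any(effect_sizes[increasing_set] <= 0) && length(increasing_set)) {
    stop("increasing_set slopes must be positive")
  }
  if (any(effect_sizes[decreasing_set] >= 0) && length(decreasing_set)) {
    stop("decreasing_set slopes must be negative")
  }
  if (noise_rank < 0 || factor_scale < 0 || diag_scale < 0 ||
      k_noise_sd < 0 || time_noise_sd < 0) {
    stop("noise scales must be non-negative")
  }
  cfg <- list(n_samples = n_samples, pmi_range = as.numeric(pmi_range),
              n_metabolites = n_metabolites,
              metabolite_names = metabolite_names,
              increasing_set = increasing_set, decreasing_set = decreasing_set,
              effect_sizes = as.numeric(effect_sizes),
              time_noise_sd = time_noise_sd,
              noise_rank = as.integer(noise_rank),
              factor_scale = factor_scale, diag_scale = diag_scale,
              k_intercept = k_intercept, k_slope = k_slope,
              k_noise_sd = k_noise_sd,
              pmi_dependent = isTRUE(pmi_dependent), seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# Draws the structural parameters (baselines, factor loadings) that define
# the cohort's noise covariance. Must be the first draws from the seeded
# stream so that oracle_rmse() can reproduce them without the sample draws.
.cohort_structure <- function(cfg) {
  p <- cfg$n_metabolites
  r <- cfg$noise_rank
  baseline <- stats::rnorm(p, mean = log(50), sd = 1)
  lambda <- if (r > 0) {
    matrix(stats::rnorm(p * r), p, r) * cfg$factor_scale
  } else {
    matrix(0, p, 0)
  }
  list(baseline = baseline, lambda = lambda)
}

#' Generate a synthetic cohort
#'
#' Draws a samples-by-metabolites concentration table with PMI (hours) and
#' potassium (mM) columns according to a [cohort_config()]. Concentrations
#' are strictly positive by construction (log-normal model). Identical
#' configurations (including seed) give bit-identical tables.
#'
#' @param cfg A [cohort_config()].
#' @return A `data.frame` of class `metabolite_table` with columns
#'   `sample_id`, `pmi_h`, `k_mM`, then one column per metabolite; the
#'   metabolite names are stored in `attr(, "metabolites")`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_samples
  p <- cfg$n_metabolites
  r <- cfg$noise_rank
  set.seed(cfg$seed)
  st <- .cohort_structure(cfg)
  pmi <- stats::runif(n, cfg$pmi_range[1], cfg$pmi_range[2])
  # For a null cohort the mean structure follows a latent PMI drawn
  # independently of the reported one: marginals unchanged, dependence gone.
  pmi_latent <- if (cfg$pmi_dependent) {
    pmi
  } else {
    stats::runif(n, cfg$pmi_range[1], cfg$pmi_range[2])
  }
  eta <- stats::rnorm(n, 0, cfg$time_noise_sd)  # per-animal clock offset
  f <- if (r > 0) matrix(stats::rnorm(n * r), n, r) else matrix(0, n, 0)
  e <- matrix(stats::rnorm(n * p), n, p) * cfg$diag_scale
  logc <- rep(1, n) %o% st$baseline +
    (pmi_latent + eta) %o% cfg$effect_sizes +
    f %*% t(st$lambda) + e
  conc <- exp(logc)
  colnames(conc) <- cfg$metabolite_names
  k <- cfg$k_intercept + cfg$k_slope * pmi_latent +
    stats::rnorm(n, 0, cfg$k_noise_sd)
  k <- pmax(k, 0.1)  # physical concentrations stay positive
  out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                    pmi_h = pmi, k_mM = k, conc,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "metabolites") <- cfg$metabolite_names
  class(out) <- c("metabolite_table", "data.frame")
  out
}

#' Generate a null cohort
#'
#' Same marginal distributions as [generate_cohort()] but with PMI
#' independent of every metabolite and of potassium. Used to calibrate
#' randomisation tests.
#'
#' @inheritParams generate_cohort
#' @return A `metabolite_table`.
#' @export
generate_null_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  cfg$pmi_dependent <- FALSE
  generate_cohort(cfg)
}

#' Extract the concentration matrix from a metabolite table
#'
#' @param table A `metabolite_table` (or any data frame with a
#'   `metabolites` attribute or metabolite columns after `sample_id`,
#'   `pmi_h`, `k_mM`).
#' @return Numeric matrix, samples by metabolites.
#' @export
metab_matrix <- function(table) {
  mets <- attr(table, "metabolites")
  if (is.null(mets)) {
    mets <- setdiff(colnames(table), c("sample_id", "pmi_h", "k_mM"))
  }
  as.matrix(as.data.frame(table)[, mets, drop = FALSE])
}

#' Closed-form oracle prediction error of a cohort configuration
#'
#' The best achievable root-mean-square error for predicting PMI from the
#' metabolite block of a cohort generated by `cfg`, i.e. the Cramer-Rao
#' bound `1 / sqrt(s' Sigma^-1 s)` where `s` is the slope vector in
#' log-concentration space and `Sigma` the noise covariance
#' (`time_noise_sd^2 s s' + Lambda Lambda' + diag_scale^2 I`). The
#' between-animal clock term is irreducible, so the bound is approximately
#' `sqrt(time_noise_sd^2 + 1/(s' Sigma_rest^-1 s))`. The factor loadings
#' are reproduced from the configuration seed, so the value is exact for
#' the corresponding cohort.
#'
#' @param cfg A [cohort_config()].
#' @return Oracle RMSE in hours (`Inf` when the configuration carries no
#'   signal).
#' @export
oracle_rmse <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  st <- .cohort_structure(cfg)
  s <- cfg$effect_sizes
  if (all(s == 0)) return(Inf)
  sigma <- cfg$time_noise_sd^2 * tcrossprod(s) +
    st$lambda %*% t(st$lambda) +
    diag(cfg$diag_scale^2, cfg$n_metabolites)
  info <- drop(crossprod(s, solve(sigma, s)))
  1 / sqrt(info)
}

#' Stratified train/test split on PMI intervals
#'
#' Splits a cohort into training and test tables, stratifying on PMI
#' intervals so that each stratum contributes to the training set in
#' proportion to its size (largest-remainder rounding to hit `n_train`
#' exactly).
#'
#' @param table A `metabolite_table`.
#' @param n_train Number of training samples (0 < n_train < n).
#' @param strata_breaks Sorted PMI break points in hours (default c(24, 48)).
#' @param seed Integer seed controlling the within-stratum draw.
#' @return List with elements `train` and `test`, both `metabolite_table`s;
#'   their union is the input and their intersection empty.
#' @export
split_stratified <- function(table, n_train, strata_breaks = c(24, 48),
                             seed = 1L) {
  n <- nrow(table)
  if (n_train <= 0 || n_train >= n) stop("n_train must be in 1..(n-1)")
  if (is.unsorted(strata_breaks, strictly = TRUE)) {
    stop("strata_breaks must be strictly increasing")
  }
  lev <- ordinal_levels(breaks = strata_breaks)
  strat <- assign_levels(table$pmi_h, lev)
  counts <- table(strat)
  if (any(counts == 0)) stop("every PMI stratum must contain samples")
  frac <- n_train / n
  raw <- as.numeric(counts) * frac
  take <- floor(raw)
  rem <- n_train - sum(take)
  if (rem > 0) {
    ord <- order(raw - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  if (any(take > counts)) stop("n_train too large for stratum sizes")
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (i in seq_along(counts)) {
    idx <- which(strat == names(counts)[i])
    train_idx <- c(train_idx, sort(sample(idx, take[i])))
  }
  train_idx <- sort(train_idx)
  mets <- attr(table, "metabolites")
  tr <- table[train_idx, , drop = FALSE]
  te <- table[-train_idx, , drop = FALSE]
  attr(tr, "metabolites") <- mets
  attr(te, "metabolites") <- mets
  class(tr) <- class(te) <- c("metabolite_table", "data.frame")
  list(train = tr, test = te)
}

#' Default synthetic peak library
#'
#' Assigns each metabolite one or two Lorentzian peak positions inside the
#' spectral region via a deterministic low-discrepancy rule. Positions are
#' synthetic, not literature chemical shifts.
#'
#' @param metabolite_names Character vector of metabolite names.
#' @param region ppm interval peaks must lie in.
#' @return `data.frame` with columns `metabolite`, `ppm`, `intensity`.
#' @export
default_peak_library <- function(metabolite_names, region = c(0.8, 9.0)) {
  p <- length(metabolite_names)
  lo <- region[1] + 0.05 * diff(region)
  hi <- region[2] - 0.05 * diff(region)
  rows <- lapply(seq_len(p), function(j) {
    n_pk <- 1L + (j %% 2L)
    frac <- ((j * c(0.381966, 0.721359))[seq_len(n_pk)] + j^2 * 1e-3) %% 1
    data.frame(metabolite = metabolite_names[j],
               ppm = lo + frac * (hi - lo),
               intensity = c(1, 0.6)[seq_len(n_pk)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate synthetic 1D spectra from a cohort
#'
#' Each sample's spectrum is the concentration-weighted sum of Lorentzian
#' peaks from the peak library plus optional Gaussian baseline noise, on a
#' uniform ppm axis.
#'
#' @param table A `metabolite_table`.
#' @param peak_library `data.frame(metabolite, ppm, intensity)`; defaults to
#'   [default_peak_library()] on the table's metabolites.
#' @param region ppm interval of the axis (default c(0.8, 9.0)).
#' @param n_points Number of axis points (default 4101).
#' @param peak_width Lorentzian half-width at half-maximum in ppm.
#' @param noise_sd Baseline noise standard deviation.
#' @param seed Seed for the baseline noise.
#' @return Object of class `spectrum_set`: list with `ppm` (ascending axis)
#'   and `intensities` (samples x points matrix).
#' @export
generate_spectra <- function(table, peak_library = NULL,
                             region = c(0.8, 9.0), n_points = 4101,
                             peak_width = 0.01, noise_sd = 0, seed = 1L) {
  conc <- metab_matrix(table)
  mets <- colnames(conc)
  if (is.null(peak_library)) peak_library <- default_peak_library(mets, region)
  if (any(peak_library$ppm < region[1] | peak_library$ppm > region[2])) {
    stop("peak positions must lie inside the spectral region")
  }
  if (!all(peak_library$metabolite %in% mets)) {
    stop("peak library refers to unknown metabolites")
  }
  ppm <- seq(region[1], region[2], length.out = n_points)
  basis <- matrix(0, length(mets), n_points)
  for (i in seq_len(nrow(peak_library))) {
    j <- match(peak_library$metabolite[i], mets)
    x0 <- peak_library$ppm[i]
    h <- peak_library$intensity[i]
    basis[j, ] <- basis[j, ] +
      h * peak_width^2 / ((ppm - x0)^2 + peak_width^2)
  }
  intens <- conc %*% basis
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    intens <- intens + matrix(stats::rnorm(length(intens), 0, noise_sd),
                              nrow(intens), ncol(intens))
  }
  rownames(intens) <- table$sample_id
  structure(list(ppm = ppm, intensities = intens), class = "spectrum_set")
}

#' Write / read a metabolite table as CSV
#'
#' Plain UTF-8 CSV with columns `sample_id`, `pmi_h`, `k_mM` (if present),
#' then one column per metabolite; '.' decimal separator.
#'
#' @param table A `metabolite_table`.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `metabolite_table`.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "pmi_h") %in% colnames(df))) {
    stop("cohort CSV must contain sample_id and pmi_h columns")
  }
  if (anyNA(df$pmi_h)) stop("missing PMI values")
  mets <- setdiff(colnames(df), c("sample_id", "pmi_h", "k_mM"))
  if (any(as.matrix(df[, mets, drop = FALSE]) <= 0)) {
    stop("concentrations must be strictly positive")
  }
  attr(df, "metabolites") <- mets
  class(df) <- c("metabolite_table", "data.frame")
  df
}
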