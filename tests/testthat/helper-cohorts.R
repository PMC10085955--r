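# Small cohort configurations used across tests.

small_cfg <- function(n = 60, p = 20, seed = 1,
                      increasing_set = seq_len(min(4, p - 1)),
                      decreasing_set = p, ...) {
  cohort_config(n_samples = n, n_metabolites = p,
                metabolite_names = sprintf("m%02d", seq_len(p)),
                increasing_set = increasing_set,
                decreasing_set = decreasing_set,
                seed = seed, ...)
}

# Noise-free monotone cohort: metabolites are exact functions of PMI.
noiseless_cfg <- function(n = 30, p = 8, seed = 1) {
  small_cfg(n = n, p = p, seed = seed,
            increasing_set = seq_len(min(3, p - 1)), decreasing_set = p,
            noise_rank = 0, factor_scale = 0, diag_scale = 0,
            time_noise_sd = 0, k_noise_sd = 0)
}

# Deterministic random regression instance on a fixed seed.
random_instance <- function(n, p, seed, coef_cols = p) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(coef_cols)
  y <- drop(X[, seq_len(coef_cols), drop = FALSE] %*% beta) + rnorm(n)
  list(X = X, y = y, beta = beta)
}
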