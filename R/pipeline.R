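#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: input cohort (a
#' `metabolite_table` or a CSV path), output directory, PMI interval
#' breaks, train/test split size, cross-validation settings, tuning grids
#' for the bounded model, significance level and seed.
#'
#' @param input A `metabolite_table` or path to a cohort CSV.
#' @param out_dir Output directory (created if missing).
#' @param breaks PMI interval breaks in hours (default c(24, 48)).
#' @param n_train Training-set size for the stratified split (default 47).
#' @param a1,a2 Ordinal model components (defaults 3 and 2).
#' @param eps1_grid,eps2_grid,a_grid,gamma_grid Bounded-model tuning grids.
#' @param cv A [cv_spec()].
#' @param alpha Significance level (default 0.05).
#' @param n_perm Permutations for randomisation tests (default 199).
#' @param seed Master seed for split and permutations.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir,
                            breaks = c(24, 48), n_train = 47,
                            a1 = 3, a2 = 2,
                            eps1_grid = c(0.01, 0.02, 0.05, 0.1),
                            eps2_grid = c(0.1, 0.3, 0.5, 0.9),
                            a_grid = 1:3, gamma_grid = c(1, 2, 3),
                            cv = cv_spec(n_repeats = 5),
                            alpha = 0.05, n_perm = 199, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(input = input, out_dir = out_dir, breaks = breaks,
                 n_train = n_train, a1 = a1, a2 = a2,
                 eps1_grid = eps1_grid, eps2_grid = eps2_grid,
                 a_grid = a_grid, gamma_grid = gamma_grid, cv = cv,
                 alpha = alpha, n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Tiny polynomial rolling hash of the deparsed configuration, for
# stamping reports (not cryptographic).
.config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), c("input", "out_dir"))]),
             collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Sequences the whole study on one cohort: stratified train/test split,
#' PCA-based outlier screening and exploration, the ordinal interval
#' classifier (train/CV/test confusion tables), the tuned bounded
#' regression model with overall and interval-wise errors and a
#' randomisation test, selectivity-ratio relevance, the univariate
#' potassium model, the potassium-residual analysis, and the combined
#' metabolites + potassium model. All artefacts are written to the output
#' directory as CSV/JSON, stamped with the seed and a configuration hash;
#' a log records each stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every fitted object and the metrics.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  cohort <- if (is.character(config$input)) read_cohort(config$input)
            else config$input
  if (!all(c("sample_id", "pmi_h") %in% colnames(cohort))) {
    stop("input table must contain sample_id and pmi_h columns")
  }
  X_all <- metab_matrix(cohort)
  if (any(X_all <= 0)) {
    stop("non-positive concentrations are incompatible with the log ",
         "transform")
  }
  logf("cohort: %d samples, %d metabolites", nrow(cohort), ncol(X_all))

  split <- split_stratified(cohort, config$n_train,
                            strata_breaks = config$breaks,
                            seed = config$seed)
  tr <- split$train
  te <- split$test
  X_tr <- metab_matrix(tr)
  X_te <- metab_matrix(te)
  lev <- ordinal_levels(breaks = config$breaks)

  # outlier screening on the centred log-concentrations
  Xl <- scale(log(X_tr), center = TRUE, scale = FALSE)
  out_rep <- detect_outliers(Xl, n_components = 2, alpha = config$alpha)
  utils::write.csv(data.frame(sample_id = tr$sample_id, t2 = out_rep$t2,
                              q = out_rep$q, t2_flag = out_rep$t2_flag,
                              q_flag = out_rep$q_flag),
                   file.path(config$out_dir, "outliers.csv"),
                   row.names = FALSE)
  logf("outliers: %d T2 flags, %d Q flags",
       sum(out_rep$t2_flag), sum(out_rep$q_flag))

  # exploratory PCA on the autoscaled metabolites
  pca <- fit_pca(apply_scaling(X_tr, fit_scaling(X_tr, "autoscale")), 2)
  logf("PCA: R2 = %.3f, Q2 = %.3f", pca$R2[2], pca$Q2[2])

  # ordinal model
  lab_tr <- assign_levels(tr$pmi_h, lev)
  lab_te <- assign_levels(te$pmi_h, lev)
  om <- fit_ordinal(X_tr, lab_tr, config$a1, config$a2)
  conf_train <- confusion(lab_tr, predict_levels(om, X_tr)$labels,
                          levels = lev$labels)
  cv_pred <- factor(rep(NA_character_, nrow(tr)), levels = lev$labels)
  cv1 <- config$cv
  cv1$stratify <- "class"
  fold_sets <- .make_fold_sets(nrow(tr), cv1, strata = lab_tr)
  assign <- fold_sets[[1]]
  for (f in seq_len(cv1$n_folds)) {
    mcv <- fit_ordinal(X_tr[assign != f, , drop = FALSE],
                       droplevels(lab_tr[assign != f]),
                       config$a1, config$a2)
    cv_pred[assign == f] <-
      predict_levels(mcv, X_tr[assign == f, , drop = FALSE])$labels
  }
  conf_cv <- confusion(lab_tr, cv_pred, levels = lev$labels)
  conf_test <- confusion(lab_te, predict_levels(om, X_te)$labels,
                         levels = lev$labels)
  for (nm in c("train", "cv", "test")) {
    ct <- switch(nm, train = conf_train, cv = conf_cv, test = conf_test)
    utils::write.csv(as.data.frame.matrix(ct$counts),
                     file.path(config$out_dir,
                               sprintf("confusion_%s.csv", nm)))
  }
  logf("ordinal: train acc %.3f, cv acc %.3f, test acc %.3f",
       conf_train$accuracy, conf_cv$accuracy, conf_test$accuracy)

  # bounded regression on the metabolites
  tuned <- tune_bounded(X_tr, tr$pmi_h, eps1_grid = config$eps1_grid,
                        eps2_grid = config$eps2_grid,
                        a_grid = config$a_grid, cv = config$cv)
  bm <- tuned$model
  pred_te <- predict_pmi(bm, X_te)
  rmsep <- sqrt(mean((te$pmi_h - pred_te)^2))
  rmsep_int <- rmse_by_interval(te$pmi_h, pred_te, config$breaks)
  utils::write.csv(data.frame(sample_id = te$sample_id,
                              pmi_true = te$pmi_h, pmi_pred = pred_te),
                   file.path(config$out_dir, "bounded_predictions.csv"),
                   row.names = FALSE)
  est <- bounded_estimator(tuned$best$eps1, tuned$best$eps2, tuned$best$A)
  cvq <- cv_spec(n_folds = config$cv$n_folds, n_repeats = 1,
                 stratify = "pmi-strata", seed = config$seed)
  stat_q2 <- function(X1, y1) repeated_kfold(est, X1, y1, cvq)$Q2
  perm <- randomisation_test(stat_q2, X_tr, tr$pmi_h, config$n_perm,
                             config$alpha, seed = config$seed)
  logf("bounded: A=%d eps1=%.3f eps2=%.3f Q2=%.3f RMSEP=%.2f perm p=%.4f",
       tuned$best$A, tuned$best$eps1, tuned$best$eps2, tuned$best$Q2,
       rmsep, perm$p_value)

  # selectivity ratio of the bounded model's predictive component
  ptm <- post_transform(bm$pls, map_forward(bm$map, tr$pmi_h))
  sr <- selectivity_ratio(ptm, X_tr, tr$pmi_h, alpha = config$alpha)
  utils::write.csv(as.data.frame(sr),
                   file.path(config$out_dir, "sr_profile.csv"),
                   row.names = FALSE)

  # potassium analyses
  k_metrics <- combined <- resid_model <- NULL
  if ("k_mM" %in% colnames(cohort)) {
    k_metrics <- fit_univariate_linear(tr$k_mM, tr$pmi_h, config$cv,
                                       x_test = te$k_mM,
                                       y_test = te$pmi_h)
    resid_model <- residual_response_model(X_tr, tr$k_mM, tr$pmi_h,
                                           A = 1, cv = config$cv,
                                           n_perm = config$n_perm,
                                           alpha = config$alpha)
    tuned_c <- tune_bounded(X_tr, tr$pmi_h, eps1_grid = config$eps1_grid,
                            eps2_grid = config$eps2_grid,
                            a_grid = config$a_grid,
                            gamma_grid = config$gamma_grid,
                            k = tr$k_mM, cv = config$cv)
    pred_c <- predict_pmi(tuned_c$model, X_te, knew = te$k_mM)
    combined <- list(tuned = tuned_c,
                     RMSEP = sqrt(mean((te$pmi_h - pred_c)^2)),
                     RMSEP_interval = rmse_by_interval(te$pmi_h, pred_c,
                                                       config$breaks))
    logf("potassium: R2=%.3f; combined RMSEP=%.2f",
         k_metrics$R2, combined$RMSEP)
  }

  metrics <- list(
    seed = config$seed, config_hash = .config_hash(config),
    n_train = nrow(tr), n_test = nrow(te),
    pca = list(R2 = pca$R2[2], Q2 = pca$Q2[2]),
    ordinal = list(
      a1 = config$a1, a2 = config$a2,
      train_accuracy = conf_train$accuracy,
      cv_accuracy = conf_cv$accuracy,
      test_accuracy = conf_test$accuracy,
      test_contiguity = conf_test$contiguity),
    bounded = list(
      A = tuned$best$A, eps1 = tuned$best$eps1, eps2 = tuned$best$eps2,
      R2 = bm$R2, Q2 = tuned$best$Q2, RMSEC = bm$RMSEC,
      RMSECV = tuned$best$RMSECV, RMSEP = rmsep,
      RMSEP_A = rmsep_int[[1]], RMSEP_B = rmsep_int[[2]],
      RMSEP_C = rmsep_int[[3]], perm_p = perm$p_value),
    potassium = if (is.null(k_metrics)) NULL else list(
      R2 = k_metrics$R2, Q2 = k_metrics$Q2, RMSEC = k_metrics$RMSEC,
      RMSECV = k_metrics$RMSECV, RMSEP = k_metrics$RMSEP,
      residual_var_ratio = resid_model$residual_var_ratio,
      residual_Q2 = if (is.null(resid_model$metrics)) NA_real_
                    else resid_model$metrics$Q2,
      residual_reliable = resid_model$reliable),
    combined = if (is.null(combined)) NULL else list(
      A = combined$tuned$best$A, gamma = combined$tuned$best$gamma,
      eps1 = combined$tuned$best$eps1, eps2 = combined$tuned$best$eps2,
      Q2 = combined$tuned$best$Q2, RMSEP = combined$RMSEP,
      RMSEP_A = combined$RMSEP_interval[[1]],
      RMSEP_B = combined$RMSEP_interval[[2]],
      RMSEP_C = combined$RMSEP_interval[[3]]))
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logf("done")
  invisible(list(split = split, outliers = out_rep, pca = pca,
                 ordinal = om,
                 confusion = list(train = conf_train, cv = conf_cv,
                                  test = conf_test),
                 bounded = tuned, sr = sr, permutation = perm,
                 potassium = k_metrics, residual = resid_model,
                 combined = combined, metrics = metrics))
}
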