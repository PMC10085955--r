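#' Ordered PMI intervals
#'
#' Defines the ordered levels used by the ordinal classifier. With the
#' default breaks c(24, 48): level A is PMI < 24 h, level B the closed
#' interval 24-48 h, level C is PMI > 48 h.
#'
#' @param breaks Sorted break points in hours (default c(24, 48)).
#' @param labels Ordered level labels; length must be `length(breaks) + 1`
#'   (default LETTERS).
#' @return Object of class `ordinal_levels` with `breaks`, `labels`,
#'   `ranks` (1..L).
#' @export
ordinal_levels <- function(breaks = c(24, 48), labels = NULL) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 1 || is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing")
  }
  L <- length(breaks) + 1L
  if (is.null(labels)) labels <- LETTERS[seq_len(L)]
  if (length(labels) != L) stop("need one label more than breaks")
  structure(list(breaks = breaks, labels = as.character(labels),
                 ranks = seq_len(L)),
            class = "ordinal_levels")
}

#' Assign PMI values to ordered intervals
#'
#' The first interval is open above (`pmi < breaks[1]`), the last open
#' below (`pmi > breaks[L-1]`), interior intervals are closed: a PMI equal
#' to a break belongs to the interval for which the break is the upper
#' endpoint, except the first break, which belongs to the second interval.
#' With breaks c(24, 48): 24 -> B and 48 -> B.
#'
#' @param pmi Numeric vector of PMI hours (>= 0).
#' @param levels An [ordinal_levels()] object.
#' @return Factor of labels with the ordered level set.
#' @export
assign_levels <- function(pmi, levels = ordinal_levels()) {
  pmi <- as.numeric(pmi)
  if (any(pmi < 0, na.rm = TRUE)) stop("PMI must be non-negative")
  if (anyNA(pmi)) stop("PMI must not contain missing values")
  idx <- 1L + findInterval(pmi, levels$breaks)
  for (j in seq_along(levels$breaks)) {
    if (j >= 2) idx[pmi == levels$breaks[j]] <- j
  }
  factor(levels$labels[idx], levels = levels$labels, ordered = TRUE)
}

#' Fit the ordinal PLS classifier
#'
#' Three-step procedure for ordinal responses with collinear, wide
#' predictor blocks: (1) PLS2-C of the predictors on the dummy-coded
#' levels with `A1` components; (2) post-transformed PLS of the resulting
#' scores on the level ranks with `A2` components, concentrating the
#' ordinal information into one predictive latent variable; (3) a Gaussian
#' naive Bayes classifier on that latent variable (class-conditional
#' means/variances, empirical priors).
#'
#' @param X Predictor matrix, raw scale.
#' @param labels Class labels, coercible to an ordered factor whose level
#'   order encodes the ranks (use [assign_levels()]).
#' @param A1 Components of the PLS2-C step.
#' @param A2 Components of the post-transformed step (A2 <= A1).
#' @param x_scaling Predictor scaling (default "autoscale").
#' @return Object of class `ordinal_model` with elements `pls2c`, `step2`
#'   (`pls_model` on the scores), `ptm`, `nb` (per-class mean, var, prior),
#'   `levels` (label set). Warns if the class means on the latent variable
#'   are not monotone in rank.
#' @export
fit_ordinal <- function(X, labels, A1, A2, x_scaling = "autoscale") {
  labels <- as.factor(labels)
  if (A2 > A1) stop("A2 must not exceed A1")
  pls2c <- fit_pls2c(X, labels, A1, x_scaling = x_scaling)
  ranks <- as.integer(labels)
  step2 <- fit_pls2(pls2c$T, ranks, A2, x_scaling = "mean_center",
                    y_scaling = "mean_center")
  ptm <- post_transform(step2, ranks)
  t_p <- ptm$t_p
  lev <- levels(labels)
  var_floor <- 1e-8 * stats::var(t_p)
  nb <- lapply(lev, function(l) {
    v <- t_p[labels == l]
    list(mean = mean(v), var = max(stats::var(v), var_floor),
         prior = length(v) / length(t_p))
  })
  names(nb) <- lev
  means <- vapply(nb, `[[`, numeric(1), "mean")
  if (is.unsorted(means) && is.unsorted(rev(means))) {
    warning("class means on the predictive latent variable are not ",
            "monotone in rank")
  }
  structure(list(pls2c = pls2c, step2 = step2, ptm = ptm, nb = nb,
                 levels = lev),
            class = "ordinal_model")
}

#' Predict PMI intervals with an ordinal model
#'
#' Projects new samples through the PLS2-C and post-transformation steps to
#' the predictive latent variable and applies the Gaussian naive Bayes
#' rule. Posterior rows sum to one; ties break toward the lower rank.
#'
#' @param model An `ordinal_model`.
#' @param Xnew New predictor matrix.
#' @return List with `labels` (ordered factor) and `posterior`
#'   (samples x levels matrix).
#' @export
predict_levels <- function(model, Xnew) {
  scores1 <- project_scores(model$pls2c, Xnew)
  t_p <- .ptpls_scores(model$ptm, scores1)
  lev <- model$levels
  dens <- vapply(lev, function(l) {
    par <- model$nb[[l]]
    par$prior * stats::dnorm(t_p, par$mean, sqrt(par$var))
  }, numeric(length(t_p)))
  dens <- matrix(dens, ncol = length(lev),
                 dimnames = list(NULL, lev))
  rs <- rowSums(dens)
  # all densities numerically zero: fall back to nearest class mean
  zero <- rs == 0
  if (any(zero)) {
    means <- vapply(model$nb, `[[`, numeric(1), "mean")
    for (i in which(zero)) {
      dens[i, which.min(abs(t_p[i] - means))] <- 1
    }
    rs <- rowSums(dens)
  }
  post <- dens / rs
  idx <- apply(post, 1, which.max)  # first max: ties toward lower rank
  list(labels = factor(lev[idx], levels = lev, ordered = TRUE),
       posterior = post)
}

#' Confusion table for ordinal predictions
#'
#' Cross-tabulates true against predicted levels and reports accuracy and
#' the contiguity of errors (fraction of misclassifications landing in an
#' adjacent level; `NaN` when there are no errors).
#'
#' @param true,predicted Label vectors of equal length over the same level
#'   set.
#' @param levels Optional character vector fixing the level order.
#' @return Object of class `confusion_table`: `counts` (true x predicted),
#'   `accuracy`, `contiguity`, `n`.
#' @export
confusion <- function(true, predicted, levels = NULL) {
  if (length(true) != length(predicted)) stop("length mismatch")
  if (is.null(levels)) {
    levels <- if (is.factor(true)) base::levels(true) else
      sort(unique(c(as.character(true), as.character(predicted))))
  }
  if (!all(as.character(true) %in% levels) ||
      !all(as.character(predicted) %in% levels)) {
    stop("unknown label")
  }
  tf <- factor(as.character(true), levels = levels)
  pf <- factor(as.character(predicted), levels = levels)
  counts <- table(true = tf, predicted = pf)
  n <- length(true)
  acc <- sum(diag(counts)) / n
  rk_t <- as.integer(tf)
  rk_p <- as.integer(pf)
  err <- rk_t != rk_p
  contig <- if (any(err)) mean(abs(rk_t[err] - rk_p[err]) == 1) else NaN
  structure(list(counts = counts, accuracy = acc, contiguity = contig,
                 n = n),
            class = "confusion_table")
}

#' Select the component numbers of the ordinal model by cross-validation
#'
#' Repeated stratified N-fold cross-validation over a grid of (A1, A2)
#' pairs, minimising an ordinal-aware cost. The default cost is the mean
#' absolute rank error |rank(true) - rank(pred)|; plain misclassification
#' rate is available as an option. Ties break toward smaller A1, then
#' smaller A2.
#'
#' @param X Predictor matrix.
#' @param labels Ordered class labels.
#' @param a1_grid,a2_grid Candidate component counts; pairs with A2 > A1
#'   are dropped. `a2_grid` defaults to `a1_grid`.
#' @param cv A [cv_spec()]; folds are stratified by class.
#' @param cost "rank" (default) or "misclassification".
#' @param x_scaling Predictor scaling.
#' @return List with `a1`, `a2`, `cost` (the winning CV cost), and
#'   `results` (grid data frame with mean CV cost per pair).
#' @export
tune_ordinal <- function(X, labels, a1_grid = 1:4, a2_grid = NULL,
                         cv = cv_spec(), cost = c("rank",
                                                  "misclassification"),
                         x_scaling = "autoscale") {
  cost <- match.arg(cost)
  labels <- as.factor(labels)
  X <- as.matrix(X)
  if (is.null(a2_grid)) a2_grid <- a1_grid
  grid <- expand.grid(a1 = a1_grid, a2 = a2_grid)
  grid <- grid[grid$a2 <= grid$a1, , drop = FALSE]
  if (nrow(grid) == 0) stop("empty component grid")
  if (min(table(labels)) < cv$n_folds) {
    stop("fold count exceeds the smallest class size")
  }
  folds <- .make_fold_sets(length(labels), cv, strata = labels)
  cost_fun <- function(true, pred) {
    if (cost == "rank") mean(abs(as.integer(true) - as.integer(pred)))
    else mean(as.character(true) != as.character(pred))
  }
  grid$cv_cost <- NA_real_
  for (i in seq_len(nrow(grid))) {
    vals <- numeric(0)
    for (assign in folds) {
      for (f in seq_len(cv$n_folds)) {
        tr <- assign != f
        m <- fit_ordinal(X[tr, , drop = FALSE], droplevels(labels[tr]),
                         grid$a1[i], grid$a2[i], x_scaling = x_scaling)
        pr <- predict_levels(m, X[!tr, , drop = FALSE])$labels
        vals <- c(vals, cost_fun(factor(labels[!tr],
                                        levels = levels(labels)),
                                 factor(as.character(pr),
                                        levels = levels(labels))))
      }
    }
    grid$cv_cost[i] <- mean(vals)
  }
  ord <- order(grid$cv_cost, grid$a1, grid$a2)
  best <- grid[ord[1], ]
  list(a1 = best$a1, a2 = best$a2, cost = best$cv_cost, results = grid)
}
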