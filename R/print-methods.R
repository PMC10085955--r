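#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS2 model: %d components, %d samples, R2 = %.3f\n",
              x$A, x$n, x$R2))
  invisible(x)
}

#' @export
print.ptpls_model <- function(x, ...) {
  cat(sprintf(
    "Post-transformed PLS: 1 predictive + %d orthogonal components, ",
    ncol(x$T_o)))
  cat(sprintf("predictive R2 = %.3f\n", x$predictive_R2))
  invisible(x)
}

#' @export
print.ordinal_model <- function(x, ...) {
  cat(sprintf("Ordinal PLS model over levels %s (A1 = %d, A2 = %d)\n",
              paste(x$levels, collapse = " < "),
              x$pls2c$A, x$step2$A))
  means <- vapply(x$nb, `[[`, numeric(1), "mean")
  cat("class means on t_p:",
      paste(sprintf("%s=%.2f", names(means), means), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.bounded_model <- function(x, ...) {
  cat(sprintf(
    "Bounded PLS model: %d components, eps1 = %.3g, eps2 = %.3g, L = %.1f h\n",
    x$A, x$map$eps1, x$map$eps2, x$map$L))
  cat(sprintf("R2 = %.3f, RMSEC = %.2f h%s\n", x$R2, x$RMSEC,
              if (is.null(x$k_scaling)) "" else
                sprintf(", potassium gamma = %g", x$gamma)))
  invisible(x)
}

#' @export
print.confusion_table <- function(x, ...) {
  print(x$counts)
  cat(sprintf("accuracy = %.3f, contiguity of errors = %s\n", x$accuracy,
              if (is.nan(x$contiguity)) "n/a (no errors)"
              else sprintf("%.2f", x$contiguity)))
  invisible(x)
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "Randomisation test: observed = %.4f, p = %.4f (%d permutations) -> %s\n",
    x$observed, x$p_value, x$n_perm,
    if (x$passed) "passed" else "not passed"))
  invisible(x)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "Outlier screen (%d components, alpha = %.2f): %d of %d T2 flags, %d Q flags\n",
    x$n_components, x$alpha, sum(x$t2_flag), length(x$t2),
    sum(x$q_flag)))
  invisible(x)
}
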