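#' @export
print.icc_a1 <- function(x, digits = 3, ...) {
  cat("Intraclass correlation ICC(A,1)",
      "(two-way random effects, single measures, absolute agreement)\n")
  if (!is.null(x$variable)) cat("Variable:", x$variable, "\n")
  cat(sprintf("Subjects: %d (%d complete)   Raters: %d   Valid cells: %.1f%%\n",
              x$n_subjects, x$n_complete, x$k_raters, x$percent_valid))
  cat(sprintf("Estimation: %s\n", x$method))
  cat(sprintf("ICC = %.*f  [%d%% CI %.*f, %.*f]  (%s)\n",
              digits, x$estimate, round(100 * x$conf.level),
              digits, x$ci[1], digits, x$ci[2], x$band))
  invisible(x)
}

#' @export
summary.icc_a1 <- function(object, ...) {
  structure(object, class = c("summary.icc_a1", "icc_a1"))
}

#' @export
print.summary.icc_a1 <- function(x, digits = 4, ...) {
  print.icc_a1(x, digits = min(digits, 3))
  cat("\nVariance components (negative estimates truncated at 0):\n")
  tab <- cbind(estimate = x$components, raw = x$components_raw)
  print(round(tab, digits))
  cat("\nMean squares used for the confidence interval:\n")
  print(round(x$ms, digits))
  if (x$method == "incomplete_mom") {
    cat(sprintf("Effective design for the interval: n = %.2f, k = %.2f (approximate)\n",
                x$n_eff, x$k_eff))
  }
  invisible(x)
}

#' @export
coef.icc_a1 <- function(object, ...) {
  c(icc = object$estimate)
}

#' Confidence interval for a fitted ICC
#'
#' @param object An [icc_a1()] fit.
#' @param parm Ignored (there is a single parameter).
#' @param level Confidence level; defaults to the level used at fit time.
#' @param ... Unused.
#' @return A 1 x 2 matrix with the lower and upper bounds.
#' @export
confint.icc_a1 <- function(object, parm, level = object$conf.level, ...) {
  ci <- if (identical(level, object$conf.level)) {
    object$ci
  } else {
    suppressWarnings(
      .icc_ci(object$ms[["msr"]], object$ms[["msc"]], object$ms[["mse"]],
              object$n_eff, object$k_eff, object$estimate, level)
    )
  }
  out <- matrix(ci, nrow = 1,
                dimnames = list("icc", sprintf("%.1f %%",
                                               100 * c((1 - level) / 2,
                                                       1 - (1 - level) / 2))))
  out
}

#' Simulate rating matrices from a fitted ICC model
#'
#' Draws complete subjects x raters matrices from the fitted two-way
#' random-effects model, using the truncated variance components and the
#' observed grand mean. Useful for parametric-bootstrap style checks.
#'
#' @param object An [icc_a1()] fit.
#' @param nsim Number of matrices to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` numeric matrices with the fitted dimensions.
#' @export
simulate.icc_a1 <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_subjects
  k <- object$k_raters
  vc <- object$components
  lapply(seq_len(nsim), function(b) {
    s <- stats::rnorm(n, 0, sqrt(vc[["subject"]]))
    r <- stats::rnorm(k, 0, sqrt(vc[["rater"]]))
    e <- matrix(stats::rnorm(n * k, 0, sqrt(vc[["error"]])), n, k)
    object$mu + outer(s, r, "+") + e
  })
}

#' Subject profile plot for a fitted ICC
#'
#' Draws each subject's ratings across raters as connected lines; tight,
#' parallel, overlapping lines correspond to high absolute agreement.
#'
#' @param x An [icc_a1()] fit.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.icc_a1 <- function(x, ...) {
  m <- x$matrix
  graphics::matplot(t(m), type = "b", lty = 1, pch = 16,
                    xaxt = "n", xlab = "rater", ylab = "rating",
                    main = sprintf("%sICC(A,1) = %.3f",
                                   if (is.null(x$variable)) "" else
                                     paste0(x$variable, ": "),
                                   x$estimate), ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
  invisible(x)
}
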