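#' Intraclass correlation ICC(A,1): two-way random effects, single
#' measures, absolute agreement
#'
#' Fits the two-way random-effects agreement model
#' \deqn{y_{ij} = \mu + a_i + b_j + e_{ij},}
#' with subjects \eqn{a_i \sim N(0, \sigma^2_s)}, raters
#' \eqn{b_j \sim N(0, \sigma^2_r)} and residuals
#' \eqn{e_{ij} \sim N(0, \sigma^2_e)}, and estimates
#' \deqn{ICC(A,1) = \sigma^2_s / (\sigma^2_s + \sigma^2_r + \sigma^2_e),}
#' the agreement expected between single ratings by different raters.
#'
#' Two estimation routes are used, recorded in the `method` field:
#' \describe{
#'   \item{`complete_anova`}{for complete matrices, the closed form
#'     \eqn{(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))} from the
#'     two-way ANOVA mean squares (McGraw & Wong's ICC(A,1)).}
#'   \item{`incomplete_mom`}{for matrices with missing cells, a
#'     method-of-moments fit on the observed incidence pattern: the
#'     subject, rater and residual sums of squares of the unbalanced
#'     layout are equated to their expectations (Henderson/Searle-style,
#'     no interaction term) and the resulting 3x3 linear system is solved
#'     for the variance components. Every observed cell contributes; no
#'     imputation, no listwise deletion. On a complete matrix this route
#'     reduces algebraically to the closed form.}
#' }
#' The reported estimate is the raw-component ratio (identical to the
#' closed form on complete data), never exceeding 1 (on tiny degenerate
#' samples it can fall below -1, as the closed form itself does); negative
#' variance components are truncated at zero in the headline `components`
#' with the untruncated values kept in `components_raw`.
#'
#' The 95% confidence interval is the F-based interval of McGraw & Wong
#' for ICC(A,1). On incomplete data the mean squares entering the interval
#' are synthesised from the variance components using the harmonic mean of
#' per-subject (and per-rater) observation counts as effective design
#' sizes; this interval is approximate.
#'
#' @param x A subjects x raters numeric matrix (`NA` = missing), e.g.
#'   from [rating_matrix()].
#' @param conf.level Confidence level for the interval (default 0.95).
#' @param method `"auto"` (closed form when complete, method of moments
#'   otherwise), `"complete"` (closed form; errors on missing cells) or
#'   `"mom"` (force the method-of-moments route, also on complete data).
#' @return An object of class `icc_a1`: a list with `estimate`, `ci`
#'   (length-2 vector), `conf.level`, `band` (see [interpret_icc()]),
#'   `components` and `components_raw` (subject/rater/error variances),
#'   `ms` (MSR, MSC, MSE used for the interval), `n_subjects` (subjects
#'   with any data), `n_complete` (subjects rated by every retained
#'   rater), `k_raters`, `percent_valid`, `mu`, `method`, `matrix` and
#'   `call`. Methods: [print()], [summary()], [coef()], [confint()],
#'   [simulate()], [plot()].
#' @examples
#' m <- cbind(r1 = c(1, 2, 3, 4), r2 = c(2, 3, 4, 5))
#' fit <- icc_a1(m)
#' coef(fit)
#' confint(fit)
#' @export
icc_a1 <- function(x, conf.level = 0.95,
                   method = c("auto", "complete", "mom")) {
  method <- match.arg(method)
  stopifnot(is.numeric(conf.level), length(conf.level) == 1L,
            conf.level > 0, conf.level < 1)
  cl <- match.call()
  vn <- attr(x, "variable_name")
  pv <- attr(x, "percent_valid")
  m <- as.matrix(unclass(x))
  storage.mode(m) <- "double"
  if (any(is.infinite(m) | is.nan(m))) stop("ratings must be finite")
  if (is.null(pv)) pv <- percent_valid(m)

  col_ok <- colSums(!is.na(m)) > 0L
  if (!all(col_ok)) {
    warning(sprintf("dropping %d rater(s) with no observed ratings",
                    sum(!col_ok)))
    m <- m[, col_ok, drop = FALSE]
  }
  row_ok <- rowSums(!is.na(m)) > 0L
  if (!all(row_ok)) {
    message(sprintf("dropping %d subject(s) with no observed ratings",
                    sum(!row_ok)))
    m <- m[row_ok, , drop = FALSE]
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("ICC undefined: need at least 2 subjects and 2 raters with data")
  }
  obs <- !is.na(m)
  vals <- m[obs]
  if (diff(range(vals)) == 0) {
    stop("ICC undefined: all observed values are identical (zero variance)")
  }
  complete <- all(obs)
  if (method == "complete" && !complete) {
    stop("method = \"complete\" requires a matrix without missing cells")
  }
  route <- if (method == "mom" || !complete) "mom" else "anova"
  fit <- if (route == "anova") .icc_complete(m) else .icc_mom(m)

  est <- min(fit$estimate, 1)
  ci <- .icc_ci(fit$msr, fit$msc, fit$mse, fit$n_eff, fit$k_eff,
                est, conf.level)
  raw <- fit$components
  out <- list(
    estimate = est,
    ci = ci,
    conf.level = conf.level,
    band = interpret_icc(est),
    components = pmax(raw, 0),
    components_raw = raw,
    ms = c(msr = fit$msr, msc = fit$msc, mse = fit$mse),
    n_subjects = n,
    n_complete = sum(rowSums(obs) == k),
    k_raters = k,
    n_eff = fit$n_eff,
    k_eff = fit$k_eff,
    percent_valid = pv,
    mu = mean(vals),
    variable = vn,
    method = if (route == "anova") "complete_anova" else "incomplete_mom",
    matrix = m,
    call = cl
  )
  class(out) <- "icc_a1"
  out
}

# Closed-form two-way ANOVA decomposition on a complete matrix.
.icc_complete <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  gm <- mean(m)
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm_ - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  list(
    estimate = est,
    components = c(subject = (msr - mse) / k,
                   rater = (msc - mse) / n,
                   error = mse),
    msr = msr, msc = msc, mse = mse, n_eff = n, k_eff = k
  )
}

# Method-of-moments variance components on an arbitrary 0/1 incidence
# pattern: equate the row, column and residual sums of squares of the
# unbalanced two-way additive layout to their expectations and solve for
# (sigma2_subject, sigma2_rater, sigma2_error).
.icc_mom <- function(m) {
  obs <- !is.na(m)
  y <- ifelse(obs, m, 0)
  N <- sum(obs)
  ri <- rowSums(obs)
  cj <- colSums(obs)
  a <- nrow(m)
  b <- ncol(m)
  Ri <- rowSums(y)
  Cj <- colSums(y)
  G <- sum(y)

  t0 <- sum(y[obs]^2)
  ta <- sum(Ri^2 / ri)
  tb <- sum(Cj^2 / cj)
  tm <- G^2 / N
  ssa <- ta - tm
  ssb <- tb - tm
  sse <- t0 - ta - tb + tm

  sr2 <- sum(ri^2) / N
  sc2 <- sum(cj^2) / N
  A <- rbind(
    c(N - sr2, a - sc2, a - 1),
    c(b - sr2, N - sc2, b - 1),
    c(sr2 - b, sc2 - a, N - a - b + 1)
  )
  comp <- tryCatch(
    solve(A, c(ssa, ssb, sse)),
    error = function(e) {
      stop("ICC undefined: the pattern of observed cells is too sparse to ",
           "separate subject, rater and error variance (singular moment ",
           "equations)")
    }
  )
  names(comp) <- c("subject", "rater", "error")
  denom <- sum(comp)
  if (denom <= 0) {
    stop("ICC undefined: nonpositive total variance estimate")
  }
  est <- comp[["subject"]] / denom

  k_eff <- a / sum(1 / ri)   # harmonic mean raters per subject
  h_c <- b / sum(1 / cj)     # harmonic mean subjects per rater
  mse <- max(comp[["error"]], 0)
  msr <- k_eff * max(comp[["subject"]], 0) + mse
  msc <- h_c * max(comp[["rater"]], 0) + mse
  list(estimate = est, components = comp,
       msr = msr, msc = msc, mse = mse, n_eff = a, k_eff = k_eff)
}

# F-based confidence interval for ICC(A,1) (McGraw & Wong). n and k may
# be effective (non-integer) design sizes on incomplete data.
.icc_ci <- function(msr, msc, mse, n, k, est, level) {
  alpha <- 1 - level
  if (msc < 1e-12 && mse < 1e-12) {
    warning("degenerate ANOVA decomposition; returning the trivial interval")
    return(c(-1, 1))
  }
  r <- min(max(est, -1 + 1e-9), 1 - 1e-9)
  aa <- k * r / (n * (1 - r))
  bb <- 1 + k * r * (n - 1) / (n * (1 - r))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  if (!is.finite(v) || v <= 0) {
    warning("degenerate ANOVA decomposition; returning the trivial interval")
    return(c(-1, 1))
  }
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  c(min(lo, est), min(1, max(hi, est)))
}

#' Qualitative interpretation band for an ICC estimate
#'
#' Maps estimates onto the conventional agreement bands: below 0.4 low,
#' 0.40--0.59 fair, 0.60--0.74 good, and 0.75 or above excellent. Each
#' boundary belongs to the upper band (0.40 is fair, 0.60 good, 0.75
#' excellent).
#'
#' @param estimate Numeric vector of ICC estimates.
#' @return Character vector with values `"low"`, `"fair"`, `"good"`,
#'   `"excellent"`.
#' @examples
#' interpret_icc(c(0.39, 0.4, 0.71, 0.957))
#' @export
interpret_icc <- function(estimate) {
  stopifnot(all(is.finite(estimate)))
  as.character(cut(estimate,
                   breaks = c(-Inf, 0.40, 0.60, 0.75, Inf),
                   labels = c("low", "fair", "good", "excellent"),
                   right = FALSE))
}

#' Item-level reliability table
#'
#' Fits [icc_a1()] to each item of the catalogue and tabulates the
#' estimates, confidence bounds, interpretation bands and percent of
#' valid subject x rater cells (over the full study grid). Items whose
#' data do not support an ICC (fewer than 2 raters or subjects with data,
#' or zero variance) are kept as rows with a missing estimate and a
#' `note` explaining why.
#'
#' @param records Validated ratings.
#' @param catalog An [item_catalog()].
#' @param conf.level Confidence level for the intervals.
#' @param sort_by `"estimate"` (descending ICC, the conventional report
#'   order) or `"catalog"` (instrument order).
#' @param digits Decimal places for the tabulated estimate and bounds
#'   (default 3, matching conventional reliability tables); use `NA` to
#'   disable rounding.
#' @return A data frame with one row per item: `item`, `label`,
#'   `subscale`, `icc`, `ci_low`, `ci_high`, `band`, `percent_valid`,
#'   `n` (subjects with any data for the item), `n_complete` (subjects
#'   rated by all raters), `method`, `note`.
#' @export
itemwise_icc <- function(records, catalog = sops_catalog(),
                         conf.level = 0.95,
                         sort_by = c("estimate", "catalog"), digits = 3) {
  sort_by <- match.arg(sort_by)
  records <- validate_ratings(records, catalog)
  subj <- sort(unique(records$subject_id))
  rat <- sort(unique(records$rater_id))
  grid <- length(subj) * length(rat)

  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    code <- catalog$item_code[i]
    d <- records[records$item_code == code & !is.na(records$rating), ]
    pv <- round(100 * nrow(d) / grid, 1)
    base <- data.frame(
      item = code, label = catalog$label[i], subscale = catalog$subscale[i],
      icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      band = NA_character_, percent_valid = pv,
      n = length(unique(d$subject_id)),
      n_complete = NA_integer_, method = NA_character_,
      note = "", stringsAsFactors = FALSE
    )
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        icc_a1(rating_matrix(records, code, catalog = catalog),
               conf.level = conf.level)
      )),
      error = function(e) conditionMessage(e)
    )
    if (is.character(fit)) {
      base$note <- fit
      return(base)
    }
    base$icc <- fit$estimate
    base$ci_low <- fit$ci[1]
    base$ci_high <- fit$ci[2]
    base$band <- fit$band
    base$n_complete <- fit$n_complete
    base$method <- fit$method
    base
  })
  out <- do.call(rbind, rows)
  if (sort_by == "estimate") {
    out <- out[order(-out$icc, catalog$interview_order, na.last = TRUE), ]
  }
  if (!is.na(digits)) {
    out$icc <- round(out$icc, digits)
    out$ci_low <- round(out$ci_low, digits)
    out$ci_high <- round(out$ci_high, digits)
  }
  rownames(out) <- NULL
  out
}
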