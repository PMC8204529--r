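#' Summary scores per subject-rater profile
#'
#' Computes the total SOPS score (sum of all 19 item ratings), the four
#' subscale totals, and the combined positive + negative + disorganization
#' total used for subthreshold status reliability. Two policies govern
#' incomplete profiles:
#' \describe{
#'   \item{`available_sum`}{sum the non-missing items (missing items
#'     contribute 0) and record how many were missing. This reproduces
#'     summary tables with 100% valid totals even when a few late
#'     interview items were skipped.}
#'   \item{`strict_missing`}{any total whose constituent items include a
#'     missing rating is itself missing.}
#' }
#' A profile with no scored items at all yields all-missing totals under
#' either policy, with a warning.
#'
#' @param records Validated ratings (see [validate_ratings()]).
#' @param policy Missing-item policy, see Details.
#' @param catalog An [item_catalog()].
#' @return A data frame of class `sops_scores`, one row per
#'   (subject, rater), with columns `subject_id`, `rater_id`,
#'   `pos_total`, `neg_total`, `dis_total`, `gen_total`, `total_sops`,
#'   `combined_pnd`, `n_missing_items` and `policy_applied`.
#' @export
score_summaries <- function(records,
                            policy = c("available_sum", "strict_missing"),
                            catalog = sops_catalog()) {
  policy <- match.arg(policy)
  records <- validate_ratings(records, catalog)
  items <- catalog$item_code
  subj <- sort(unique(records$subject_id))
  rat <- sort(unique(records$rater_id))
  pair_lvls <- as.vector(t(outer(subj, rat, paste, sep = "\r")))
  pair <- paste(records$subject_id, records$rater_id, sep = "\r")
  m <- matrix(NA_integer_, length(pair_lvls), length(items),
              dimnames = list(pair_lvls, items))
  m[cbind(match(pair, pair_lvls), match(records$item_code, items))] <-
    records$rating

  idx <- split(seq_along(items), catalog$subscale)
  sum_block <- function(cols) {
    blk <- m[, cols, drop = FALSE]
    if (policy == "available_sum") {
      rowSums(blk, na.rm = TRUE)
    } else {
      rowSums(blk)
    }
  }
  pos <- sum_block(idx[["positive"]])
  neg <- sum_block(idx[["negative"]])
  dis <- sum_block(idx[["disorganization"]])
  gen <- sum_block(idx[["general"]])
  tot <- sum_block(seq_along(items))
  n_miss <- rowSums(is.na(m))

  none <- rowSums(!is.na(m)) == 0L
  if (any(none)) {
    warning(sprintf("%d subject-rater profile(s) have no scored items; totals set to missing",
                    sum(none)))
    pos[none] <- neg[none] <- dis[none] <- gen[none] <- tot[none] <- NA
  }
  pnd <- pos + neg + dis

  ids <- do.call(rbind, strsplit(rownames(m), "\r", fixed = TRUE))
  out <- data.frame(
    subject_id = ids[, 1], rater_id = ids[, 2],
    pos_total = as.numeric(pos), neg_total = as.numeric(neg),
    dis_total = as.numeric(dis), gen_total = as.numeric(gen),
    total_sops = as.numeric(tot), combined_pnd = as.numeric(pnd),
    n_missing_items = as.integer(n_miss),
    policy_applied = policy,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("sops_scores", "data.frame")
  out
}

.summary_vars <- c("total_sops", "pos_total", "neg_total", "dis_total",
                   "gen_total", "combined_pnd")

#' Subjects-by-raters matrix for one variable
#'
#' Arranges one target variable -- a single item's ratings or a summary
#' score -- as a subjects x raters grid suitable for [icc_a1()]. Cells
#' with no observation are `NA`; subject rows with no data at all are
#' dropped (with a message), but the percent of valid cells is recorded
#' over the full grid before dropping.
#'
#' @param records Validated ratings.
#' @param variable Either an item code from the catalogue or one of
#'   `"total_sops"`, `"pos_total"`, `"neg_total"`, `"dis_total"`,
#'   `"gen_total"`, `"combined_pnd"`.
#' @param policy Missing-item policy passed to [score_summaries()] when
#'   `variable` is a summary score.
#' @param catalog An [item_catalog()].
#' @return A numeric matrix of class `rating_matrix` with subject row
#'   names and rater column names, and attributes `variable_name` and
#'   `percent_valid`.
#' @export
rating_matrix <- function(records, variable,
                          policy = c("available_sum", "strict_missing"),
                          catalog = sops_catalog()) {
  policy <- match.arg(policy)
  if (variable %in% catalog$item_code) {
    records <- validate_ratings(records, catalog)
    d <- records[records$item_code == variable,
                 c("subject_id", "rater_id", "rating")]
    names(d)[3] <- "value"
  } else if (variable %in% .summary_vars) {
    sc <- score_summaries(records, policy, catalog)
    d <- sc[, c("subject_id", "rater_id", variable)]
    names(d)[3] <- "value"
  } else {
    stop("unknown variable: ", variable)
  }
  subj <- sort(unique(d$subject_id))
  rat <- sort(unique(d$rater_id))
  m <- matrix(NA_real_, length(subj), length(rat),
              dimnames = list(subj, rat))
  m[cbind(match(d$subject_id, subj), match(d$rater_id, rat))] <- d$value

  pv <- percent_valid(m)
  empty <- rowSums(!is.na(m)) == 0L
  if (any(empty)) {
    message(sprintf("dropping %d subject(s) with no data for %s: %s",
                    sum(empty), variable,
                    paste(rownames(m)[empty], collapse = ", ")))
    m <- m[!empty, , drop = FALSE]
  }
  if (ncol(m) < 2L || sum(rowSums(!is.na(m)) > 0L) < 2L) {
    stop("ICC undefined: need data from at least 2 subjects and 2 raters for ",
         variable)
  }
  attr(m, "variable_name") <- variable
  attr(m, "percent_valid") <- pv
  class(m) <- c("rating_matrix", class(m))
  m
}

#' Percentage of valid (non-missing) cells
#'
#' The share of subject x rater cells carrying an observed value,
#' reported to one decimal place, e.g. 52 valid cells of 54 give 96.3.
#'
#' @param x A matrix (or vector) of values with `NA` for missing cells.
#' @return A single number in \[0, 100\].
#' @export
percent_valid <- function(x) {
  if (length(x) == 0L) stop("empty matrix")
  round(100 * sum(!is.na(x)) / length(x), 1)
}
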