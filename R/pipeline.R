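#' Prevalence of consensus subthreshold categories
#'
#' Counts subjects per category and reports whole-number percentages, in
#' the fixed category order npro, neg_dis, pos, pos_neg_dis, acute_pos.
#'
#' @param statuses A data frame with columns `subject_id`, `category`
#'   (one row per subject, e.g. from [consensus_status()]), or a
#'   character vector of categories.
#' @return A data frame with columns `category`, `n`, `percent`.
#' @examples
#' prevalence_summary(rep(c("npro", "neg_dis", "pos", "pos_neg_dis"),
#'                        c(7, 6, 3, 2)))
#' @export
prevalence_summary <- function(statuses) {
  cats <- if (is.data.frame(statuses)) statuses$category else
    as.character(statuses)
  if (length(cats) == 0L) {
    warning("no statuses supplied; empty prevalence table")
    return(data.frame(category = character(0), n = integer(0),
                      percent = numeric(0)))
  }
  bad <- setdiff(unique(cats), .status_levels)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  counts <- table(factor(cats, levels = .status_levels))
  data.frame(
    category = .status_levels,
    n = as.integer(counts),
    percent = round(100 * as.integer(counts) / length(cats)),
    stringsAsFactors = FALSE
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
  })
}

# Itemwise ICC restricted to one stratum of subjects; rows become
# "insufficient data" when the stratum cannot support estimation.
.stratum_item_table <- function(records, subjects, catalog, conf.level) {
  empty <- itemwise_icc(records[0, ], catalog, conf.level,
                        sort_by = "catalog")
  if (length(subjects) < 3L) {
    empty$note <- "insufficient data: fewer than 3 subjects in stratum"
    empty$percent_valid <- NA_real_
    empty$n <- length(subjects)
    return(empty)
  }
  rec <- records[records$subject_id %in% subjects, ]
  itemwise_icc(rec, catalog, conf.level, sort_by = "catalog")
}

#' Run the full reliability study
#'
#' Orchestrates the whole analysis on one long-format ratings table:
#' summary scoring, scale/subscale and item-level ICC(A,1) tables,
#' per-rater subthreshold status classification with a cross-rater
#' agreement grid, status-level ICCs (on the combined
#' positive + negative + disorganization totals and, separately, on the
#' ordinal category codes -- the two are never conflated), consensus
#' prevalence, and a CHR / non-CHR stratified re-analysis of the item
#' table. The run is deterministic given its inputs.
#'
#' @param ratings Path to a ratings CSV (see [read_ratings()]) or an
#'   in-memory ratings data frame.
#' @param catalog An [item_catalog()].
#' @param policy Missing-item policy for summary scores
#'   (see [score_summaries()]).
#' @param consensus_method Consensus operator for the per-subject status
#'   (see [consensus_status()]).
#' @param conf.level Confidence level for all intervals.
#' @param item_order Ordering of the item table, `"estimate"` or
#'   `"catalog"`.
#' @return An object of class `sops_study`: list with `scale_table`
#'   (Total SOPS + the four subscales), `item_table`, `status_icc`,
#'   `agreement` (a [status_agreement()] object), `consensus`,
#'   `prevalence`, `chr` (the [chr_split()]), `chr_item_table`
#'   (per-stratum item ICCs and their differences, with the count of
#'   items comparable across strata), `scores`, `incomplete` flag and
#'   `metadata`.
#' @export
run_study <- function(ratings, catalog = sops_catalog(),
                      policy = c("available_sum", "strict_missing"),
                      consensus_method = c("median_item",
                                           "majority_category"),
                      conf.level = 0.95,
                      item_order = c("estimate", "catalog")) {
  policy <- match.arg(policy)
  consensus_method <- match.arg(consensus_method)
  item_order <- match.arg(item_order)

  records <- .stage("load", {
    if (is.character(ratings)) read_ratings(ratings, catalog)
    else validate_ratings(ratings, catalog)
  })
  if (length(unique(records$rater_id)) < 2L) {
    stop("stage 'load': need ratings from at least 2 raters")
  }

  scores <- .stage("score", score_summaries(records, policy, catalog))

  scale_vars <- c("total_sops", "dis_total", "pos_total", "neg_total",
                  "gen_total")
  scale_labs <- c("Total SOPS", "Total D", "Total P", "Total N", "Total G")
  scale_desc <- c("Scale of prodromal symptoms (19 items)",
                  "Disorganization symptoms subscale",
                  "Positive symptoms subscale",
                  "Negative symptoms subscale",
                  "General symptoms subscale")
  scale_table <- .stage("scale_icc", {
    rows <- lapply(seq_along(scale_vars), function(i) {
      fit <- tryCatch(
        suppressMessages(suppressWarnings(icc_a1(
          rating_matrix(records, scale_vars[i], policy, catalog),
          conf.level = conf.level
        ))),
        error = function(e) conditionMessage(e)
      )
      if (is.character(fit)) {
        data.frame(scale = scale_labs[i], description = scale_desc[i],
                   icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   band = NA_character_, percent_valid = NA_real_,
                   n = NA_integer_, n_complete = NA_integer_,
                   method = NA_character_, note = fit,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(scale = scale_labs[i], description = scale_desc[i],
                   icc = round(fit$estimate, 3),
                   ci_low = round(fit$ci[1], 3),
                   ci_high = round(fit$ci[2], 3),
                   band = fit$band, percent_valid = fit$percent_valid,
                   n = fit$n_subjects, n_complete = fit$n_complete,
                   method = fit$method, note = "",
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  })

  item_table <- .stage("item_icc",
                       itemwise_icc(records, catalog, conf.level,
                                    sort_by = item_order))

  statuses <- .stage("classify", classify_ratings(records, catalog))
  agreement <- .stage("agreement", status_agreement(statuses))
  consensus <- .stage("consensus",
                      consensus_status(records, consensus_method, catalog))
  prevalence <- .stage("prevalence", prevalence_summary(consensus))
  split <- .stage("chr_split", chr_split(consensus))

  status_icc <- .stage("status_icc", {
    one <- function(measure, m) {
      fit <- tryCatch(
        suppressMessages(suppressWarnings(icc_a1(m, conf.level))),
        error = function(e) conditionMessage(e)
      )
      if (is.character(fit)) {
        data.frame(measure = measure, icc = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, band = NA_character_,
                   percent_valid = NA_real_, n = NA_integer_,
                   note = fit, stringsAsFactors = FALSE)
      } else {
        data.frame(measure = measure, icc = round(fit$estimate, 3),
                   ci_low = round(fit$ci[1], 3),
                   ci_high = round(fit$ci[2], 3), band = fit$band,
                   percent_valid = fit$percent_valid, n = fit$n_subjects,
                   note = "", stringsAsFactors = FALSE)
      }
    }
    mp <- tryCatch(
      suppressMessages(rating_matrix(records, "combined_pnd", policy,
                                     catalog)),
      error = function(e) NULL
    )
    subj <- sort(unique(statuses$subject_id))
    rat <- sort(unique(statuses$rater_id))
    mc <- matrix(NA_real_, length(subj), length(rat),
                 dimnames = list(subj, rat))
    mc[cbind(match(statuses$subject_id, subj),
             match(statuses$rater_id, rat))] <- statuses$ordinal_code
    rbind(
      one("combined_pnd_total",
          if (is.null(mp)) matrix(NA_real_, 1, 1) else mp),
      one("status_category_code", mc)
    )
  })

  chr_item_table <- .stage("chr_stratified", {
    t_chr <- .stratum_item_table(records, split$chr, catalog, conf.level)
    t_non <- .stratum_item_table(records, split$non_chr, catalog,
                                 conf.level)
    if (split$n_chr < 3L || split$n_non_chr < 3L) {
      warning("a CHR stratum has fewer than 3 subjects; stratified ICCs not estimable")
    }
    comparable <- !is.na(t_chr$icc) & !is.na(t_non$icc)
    tab <- data.frame(
      item = t_chr$item, label = t_chr$label,
      icc_chr = t_chr$icc, icc_non_chr = t_non$icc,
      difference = round(t_chr$icc - t_non$icc, 3),
      comparable = comparable,
      note_chr = t_chr$note, note_non_chr = t_non$note,
      stringsAsFactors = FALSE
    )
    attr(tab, "n_comparable") <- sum(comparable)
    tab
  })

  out <- list(
    scale_table = scale_table,
    item_table = item_table,
    status_icc = status_icc,
    agreement = agreement,
    consensus = consensus,
    prevalence = prevalence,
    chr = split,
    chr_item_table = chr_item_table,
    scores = scores,
    incomplete = any(is.na(scale_table$icc)) || any(is.na(item_table$icc)) ||
      any(is.na(status_icc$icc)),
    metadata = list(
      policy = policy,
      consensus_method = consensus_method,
      conf.level = conf.level,
      item_order = item_order,
      n_subjects = length(unique(records$subject_id)),
      n_raters = length(unique(records$rater_id)),
      n_records = nrow(records),
      n_comparable_items = attr(chr_item_table, "n_comparable"),
      package_version = as.character(utils::packageVersion("sopsrel"))
    )
  )
  class(out) <- "sops_study"
  out
}

#' @export
print.sops_study <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("SOPS inter-rater reliability study: %d subjects, %d raters, %d rating records\n",
              md$n_subjects, md$n_raters, md$n_records))
  if (x$incomplete) cat("NOTE: report is incomplete; some ICCs were not estimable (see notes)\n")
  cat("\nScale and subscale ICC(A,1):\n")
  print(x$scale_table[, c("scale", "icc", "ci_low", "ci_high", "band",
                          "percent_valid")], row.names = FALSE)
  cat("\nItem ICC range:",
      sprintf("%.3f - %.3f", min(x$item_table$icc, na.rm = TRUE),
              max(x$item_table$icc, na.rm = TRUE)), "\n")
  cat("\nSubthreshold status ICCs:\n")
  print(x$status_icc[, c("measure", "icc", "ci_low", "ci_high", "band")],
        row.names = FALSE)
  cat(sprintf("\nStatus agreement: %.0f%% of subjects unanimous; CHR %d / non-CHR %d\n",
              100 * x$agreement$unanimity, x$chr$n_chr, x$chr$n_non_chr))
  cat("\nConsensus prevalence:\n")
  print(x$prevalence, row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes the report tables as CSV files (`scale_table.csv`,
#' `item_table.csv`, `status_table.csv`, `status_icc.csv`,
#' `prevalence.csv`, `chr_item_table.csv`, `scores.csv`) plus the full
#' report, configuration echo included, as `report.json`. Output is
#' byte-identical across runs on identical input.
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "sops_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) {
    p <- file.path(dir, f)
    utils::write.csv(d, p, row.names = FALSE, na = "")
    p
  }
  paths <- c(
    w(study$scale_table, "scale_table.csv"),
    w(study$item_table, "item_table.csv"),
    w(study$agreement$table, "status_table.csv"),
    w(study$status_icc, "status_icc.csv"),
    w(study$prevalence, "prevalence.csv"),
    w(study$chr_item_table, "chr_item_table.csv"),
    w(study$scores, "scores.csv")
  )
  rep <- list(
    metadata = study$metadata,
    scale_table = study$scale_table,
    item_table = study$item_table,
    status_icc = study$status_icc,
    status_table = study$agreement$table,
    unanimity = study$agreement$unanimity,
    consensus = study$consensus,
    prevalence = study$prevalence,
    chr = study$chr,
    chr_item_table = study$chr_item_table,
    incomplete = study$incomplete
  )
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(rep, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(paths, jp))
}
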