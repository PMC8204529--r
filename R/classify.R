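.status_levels <- c("npro", "neg_dis", "pos", "pos_neg_dis", "acute_pos")

# Decision rules on the qualifying-item counts. `any6`: any positive item
# rated 6; `n_pos`: positive items rated 3-5; `n_nd`: negative or
# disorganization items rated 3-6. The acute rule is unconditional; the
# combined category is the conjunction of the positive and
# negative/disorganized rules and is checked before either alone, so the
# five categories partition all complete profiles.
.classify_counts <- function(any6, n_pos, n_nd) {
  if (any6) return("acute_pos")
  if (n_pos >= 1L && n_nd >= 2L) return("pos_neg_dis")
  if (n_pos >= 1L) return("pos")
  if (n_nd >= 2L) return("neg_dis")
  "npro"
}

#' Subthreshold psychotic symptom status of one rating profile
#'
#' Assigns a subject-rater item profile to one of five mutually exclusive
#' categories based on the positive (P), negative (N) and disorganization
#' (D) items; general (G) items never influence the category:
#' \describe{
#'   \item{`acute_pos`}{at least one positive item rated 6 (overrides all
#'     other rules);}
#'   \item{`pos_neg_dis`}{at least one positive item rated 3--5 and at
#'     least two negative/disorganization items rated 3--6;}
#'   \item{`pos`}{at least one positive item rated 3--5 (and fewer than
#'     two qualifying negative/disorganization items);}
#'   \item{`neg_dis`}{at least two negative/disorganization items rated
#'     3--6, with no positive item rated 3 or above;}
#'   \item{`npro`}{none of the above (not psychosis-prone).}
#' }
#' Missing items are counted as non-qualifying (no imputation). The
#' `complete` flag is `FALSE` when some assignment of the missing items
#' could change the category, i.e. the label is sensitive to the
#' unscored items.
#'
#' @param profile Either a named numeric vector of ratings (names are
#'   item codes; items may be omitted or `NA`) or a data frame with
#'   columns `item_code` and `rating` for a single subject-rater.
#' @param catalog An [item_catalog()].
#' @return An object of class `subthreshold_status`: list with
#'   `category`, `ordinal_code` (0 = npro ... 4 = acute_pos, a reporting
#'   convention, not a clinical severity claim), `complete`, and the
#'   qualifying counts `n_acute`, `n_pos`, `n_neg_dis`.
#' @examples
#' classify_status(c(P1 = 4, N1 = 3, N2 = 6))
#' @export
classify_status <- function(profile, catalog = sops_catalog()) {
  if (is.data.frame(profile)) {
    v <- rep(NA_real_, nrow(catalog))
    names(v) <- catalog$item_code
    idx <- match(profile$item_code, catalog$item_code)
    if (anyNA(idx)) {
      stop("unknown item code(s): ",
           paste(unique(profile$item_code[is.na(idx)]), collapse = ", "))
    }
    v[idx] <- profile$rating
    profile <- v
  } else {
    bad <- setdiff(names(profile), catalog$item_code)
    if (length(bad)) {
      stop("unknown item code(s): ", paste(bad, collapse = ", "))
    }
    v <- rep(NA_real_, nrow(catalog))
    names(v) <- catalog$item_code
    v[names(profile)] <- profile
    profile <- v
  }
  p <- profile[.catalog_codes(catalog, "positive")]
  nd <- profile[.catalog_codes(catalog, c("negative", "disorganization"))]
  if (all(is.na(c(p, nd)))) {
    stop("status undefined: all positive/negative/disorganization items missing")
  }
  any6 <- any(p == 6, na.rm = TRUE)
  n_pos <- sum(p >= 3 & p <= 5, na.rm = TRUE)
  n_nd <- sum(nd >= 3 & nd <= 6, na.rm = TRUE)
  category <- .classify_counts(any6, n_pos, n_nd)

  # Sensitivity to missing items: the counts are monotone in any fill-in,
  # so trying the extreme assignments (each missing positive item as a 6,
  # as a 3, or non-qualifying; each missing neg/dis item as qualifying or
  # not) covers every reachable category.
  n_miss_p <- sum(is.na(p))
  n_miss_nd <- sum(is.na(nd))
  cats <- character(0)
  for (e6 in unique(c(0L, min(1L, n_miss_p)))) {
    for (e35 in unique(c(0L, n_miss_p - e6))) {
      for (end in unique(c(0L, n_miss_nd))) {
        cats <- c(cats, .classify_counts(any6 || e6 > 0L,
                                         n_pos + e35, n_nd + end))
      }
    }
  }
  out <- list(
    category = category,
    ordinal_code = match(category, .status_levels) - 1L,
    complete = length(unique(cats)) == 1L,
    n_acute = sum(p == 6, na.rm = TRUE),
    n_pos = n_pos,
    n_neg_dis = n_nd
  )
  class(out) <- "subthreshold_status"
  out
}

#' @export
print.subthreshold_status <- function(x, ...) {
  cat(sprintf("subthreshold status: %s (ordinal code %d)%s\n",
              x$category, x$ordinal_code,
              if (x$complete) "" else "  [incomplete profile: category could change]"))
  invisible(x)
}

#' Classify every subject-rater profile in a ratings table
#'
#' @param records Validated ratings.
#' @param catalog An [item_catalog()].
#' @return A data frame with one row per (subject, rater):
#'   `subject_id`, `rater_id`, `category`, `ordinal_code`, `complete`.
#' @export
classify_ratings <- function(records, catalog = sops_catalog()) {
  records <- validate_ratings(records, catalog)
  key <- interaction(records$subject_id, records$rater_id, drop = TRUE,
                     sep = "\r")
  parts <- split(records, key)
  rows <- lapply(parts, function(d) {
    st <- classify_status(d[, c("item_code", "rating")], catalog)
    data.frame(subject_id = d$subject_id[1], rater_id = d$rater_id[1],
               category = st$category, ordinal_code = st$ordinal_code,
               complete = st$complete, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$rater_id), ]
  rownames(out) <- NULL
  out
}

#' Cross-rater agreement on subthreshold status
#'
#' Tabulates each subject's category by rater, flags unanimous subjects,
#' and, where raters disagree, names the raters deviating from the modal
#' category.
#'
#' @param statuses A data frame with columns `subject_id`, `rater_id`,
#'   `category`, e.g. from [classify_ratings()].
#' @return An object of class `status_agreement`: list with `table` (one
#'   row per subject: one column per rater, `unanimous`, `note`) and
#'   `unanimity` (fraction of unanimous subjects).
#' @export
status_agreement <- function(statuses) {
  stopifnot(all(c("subject_id", "rater_id", "category") %in% names(statuses)))
  subj <- sort(unique(statuses$subject_id))
  rat <- sort(unique(statuses$rater_id))
  if (length(rat) < 2L) stop("need statuses from at least 2 raters")
  w <- matrix(NA_character_, length(subj), length(rat),
              dimnames = list(subj, rat))
  w[cbind(match(statuses$subject_id, subj),
          match(statuses$rater_id, rat))] <- statuses$category
  unan <- apply(w, 1, function(z) length(unique(z[!is.na(z)])) == 1L)
  note <- vapply(seq_along(subj), function(i) {
    z <- w[i, ]
    if (unan[i]) return("")
    tab <- sort(table(z), decreasing = TRUE)
    if (sum(tab == tab[1]) > 1L) return("no majority category")
    off <- names(z)[!is.na(z) & z != names(tab)[1]]
    sprintf("rater(s) %s differ from majority category %s",
            paste(off, collapse = ", "), names(tab)[1])
  }, character(1))
  tab <- data.frame(subject_id = subj, w, unanimous = unan, note = note,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = NULL)
  out <- list(table = tab, unanimity = mean(unan))
  class(out) <- "status_agreement"
  out
}

#' @export
print.status_agreement <- function(x, ...) {
  cat(sprintf("Status agreement across raters: %.0f%% of %d subjects unanimous\n",
              100 * x$unanimity, nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Mechanical consensus status per subject
#'
#' Collapses the raters' item profiles to one status per subject. This is
#' plumbing for analyses that need a single per-subject label (prevalence,
#' CHR stratification); it approximates, but is not, a clinical
#' consensus-by-discussion process.
#'
#' \describe{
#'   \item{`median_item`}{takes the per-item median of the non-missing
#'     ratings (for an even number of raters, the lower of the two middle
#'     values) and classifies the median profile;}
#'   \item{`majority_category`}{classifies each rater's profile and takes
#'     the modal category; ties are broken toward the most severe ordinal
#'     code (a documented convention).}
#' }
#'
#' @param records Validated ratings covering at least 2 raters.
#' @param method Consensus operator, see Details.
#' @param catalog An [item_catalog()].
#' @return A data frame with one row per subject: `subject_id`,
#'   `category`, `ordinal_code`, `complete`.
#' @export
consensus_status <- function(records,
                             method = c("median_item", "majority_category"),
                             catalog = sops_catalog()) {
  method <- match.arg(method)
  records <- validate_ratings(records, catalog)
  if (length(unique(records$rater_id)) < 2L) {
    stop("consensus requires at least 2 raters")
  }
  low_median <- function(z) {
    z <- sort(z[!is.na(z)])
    if (length(z) == 0L) return(NA_real_)
    z[ceiling(length(z) / 2)]
  }
  subj <- sort(unique(records$subject_id))
  rows <- lapply(subj, function(s) {
    d <- records[records$subject_id == s, ]
    if (method == "median_item") {
      med <- tapply(d$rating, factor(d$item_code, levels = catalog$item_code),
                    low_median)
      prof <- as.numeric(med)
      names(prof) <- catalog$item_code
      prof <- prof[!is.na(prof)]
      st <- classify_status(prof, catalog)
      comp <- st$complete
      cat_ <- st$category
      code <- st$ordinal_code
    } else {
      per <- classify_ratings(d, catalog)
      tab <- table(per$category)
      top <- names(tab)[tab == max(tab)]
      cat_ <- top[which.max(match(top, .status_levels))]
      code <- match(cat_, .status_levels) - 1L
      comp <- all(per$complete)
    }
    data.frame(subject_id = s, category = cat_, ordinal_code = code,
               complete = comp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split subjects into CHR and non-CHR sets
#'
#' Clinical high risk (CHR) is any subject whose consensus status is a
#' subthreshold category other than `npro`.
#'
#' @param statuses A data frame with columns `subject_id` and `category`
#'   (one row per subject), e.g. from [consensus_status()].
#' @return A list with `chr` and `non_chr` (subject id vectors) and the
#'   counts `n_chr`, `n_non_chr`.
#' @export
chr_split <- function(statuses) {
  stopifnot(all(c("subject_id", "category") %in% names(statuses)))
  if (anyDuplicated(statuses$subject_id)) {
    stop("chr_split expects one consensus status per subject")
  }
  is_chr <- statuses$category != "npro"
  out <- list(
    chr = statuses$subject_id[is_chr],
    non_chr = statuses$subject_id[!is_chr],
    n_chr = sum(is_chr),
    n_non_chr = sum(!is_chr)
  )
  out
}
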