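# Independent oracles used to cross-check the package implementations.
# These are deliberately written from first principles, with explicit
# loops, and share no code with the package internals.

# From-scratch sums-of-squares two-way ANOVA and the single-measures
# absolute-agreement ICC, computed cell by cell.
oracle_icc_ss <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_subj <- 0
  for (i in seq_len(n)) {
    ri <- sum(m[i, ]) / k
    ss_subj <- ss_subj + k * (ri - grand)^2
  }
  ss_rat <- 0
  for (j in seq_len(k)) {
    cj <- sum(m[, j]) / n
    ss_rat <- ss_rat + n * (cj - grand)^2
  }
  ss_tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ss_tot <- ss_tot + (m[i, j] - grand)^2
    }
  }
  ss_err <- ss_tot - ss_subj - ss_rat
  msr <- ss_subj / (n - 1)
  msc <- ss_rat / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Same quantity via stats::aov mean squares; used to vouch for
# oracle_icc_ss itself.
oracle_icc_aov <- function(m) {
  d <- data.frame(
    y = as.vector(m),
    s = factor(rep(seq_len(nrow(m)), ncol(m))),
    r = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(stats::aov(y ~ s + r, data = d))[[1]]
  msr <- tab["s", "Mean Sq"]
  msc <- tab["r", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m)
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Random complete integer rating matrix that is not constant.
random_rating_matrix <- function(n, k, max_rating = 6) {
  repeat {
    m <- matrix(sample(0:max_rating, n * k, replace = TRUE), n, k)
    if (diff(range(m)) > 0) return(m)
  }
}

# Rule oracle for the subthreshold status of one profile, written as a
# direct transcription of the clinical rules (missing = non-qualifying).
oracle_status <- function(p, nd) {
  p <- p[!is.na(p)]
  nd <- nd[!is.na(nd)]
  has_acute <- FALSE
  for (v in p) if (v == 6) has_acute <- TRUE
  n_pos <- 0
  for (v in p) if (v >= 3 && v <= 5) n_pos <- n_pos + 1
  n_nd <- 0
  for (v in nd) if (v >= 3 && v <= 6) n_nd <- n_nd + 1
  if (has_acute) {
    "acute_pos"
  } else if (n_pos >= 1 && n_nd >= 2) {
    "pos_neg_dis"
  } else if (n_pos >= 1) {
    "pos"
  } else if (n_nd >= 2) {
    "neg_dis"
  } else {
    "npro"
  }
}

# Build a named full P/N/D/G profile from positive and neg/dis value
# vectors (G items fixed at 0 unless supplied).
make_profile <- function(p = rep(0, 5), nd = rep(0, 10), g = rep(0, 4)) {
  stats::setNames(
    c(p, nd[1:6], nd[7:10], g),
    c(paste0("P", 1:5), paste0("N", 1:6), paste0("D", 1:4), paste0("G", 1:4))
  )
}

# Long records for a full grid given a subjects x raters matrix of a
# single item's ratings.
records_from_item_matrix <- function(m, item = "P1") {
  data.frame(
    subject_id = rep(rownames(m), ncol(m)),
    rater_id = rep(colnames(m), each = nrow(m)),
    item_code = item,
    rating = as.vector(m),
    stringsAsFactors = FALSE
  )
}

# Complete records where every rater gives the subject's base profile.
identical_rater_records <- function(profiles, raters = c("R1", "R2", "R3")) {
  # profiles: named list subject_id -> named rating vector
  rows <- list()
  for (s in names(profiles)) {
    for (r in raters) {
      rows[[paste(s, r)]] <- data.frame(
        subject_id = s, rater_id = r,
        item_code = names(profiles[[s]]),
        rating = as.numeric(profiles[[s]]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
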