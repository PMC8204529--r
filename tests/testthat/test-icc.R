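test_that("perfect agreement gives ICC 1 with upper bound 1", {
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  fit <- suppressWarnings(icc_a1(m))
  expect_equal(fit$estimate, 1.0)
  expect_equal(fit$ci[2], 1.0)
  expect_equal(fit$band, "excellent")
})

test_that("a constant rater offset pushes absolute agreement below 1", {
  m <- cbind(c(0, 1, 2, 3), c(2, 3, 4, 5))
  fit <- icc_a1(m)
  expect_lt(fit$estimate, 1)
  expect_equal(fit$estimate, oracle_icc_ss(m), tolerance = 1e-12)
  expect_equal(fit$estimate, oracle_icc_aov(m), tolerance = 1e-12)
})

test_that("the loop-based oracle agrees with the aov-based oracle", {
  set.seed(20)
  for (rep in 1:100) {
    m <- random_rating_matrix(sample(3:6, 1), sample(2:4, 1))
    expect_equal(oracle_icc_ss(m), oracle_icc_aov(m), tolerance = 1e-10)
  }
})

test_that("estimate is invariant to translation, scaling and permutation", {
  set.seed(21)
  m <- matrix(rnorm(18 * 3, 3, 1.3), 18, 3)
  e0 <- icc_a1(m)$estimate
  expect_equal(icc_a1(m + 17.3)$estimate, e0, tolerance = 1e-10)
  expect_equal(icc_a1(m * 4.2)$estimate, e0, tolerance = 1e-10)
  expect_equal(icc_a1(m[sample(18), ])$estimate, e0, tolerance = 1e-10)
  expect_equal(icc_a1(m[, sample(3)])$estimate, e0, tolerance = 1e-10)
  # and the same holds through the incomplete-data route
  m[2, 3] <- NA
  e1 <- icc_a1(m)$estimate
  expect_equal(icc_a1(m + 5)$estimate, e1, tolerance = 1e-10)
  expect_equal(icc_a1(m * 0.25)$estimate, e1, tolerance = 1e-10)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(icc_a1(matrix(2, 5, 3)), "identical")
  expect_error(icc_a1(matrix(c(1, 2, 3, 4), 4, 1)), "2 .*raters")
  m <- cbind(c(1, 2, 3), c(1, 3, 2), c(NA, NA, NA))
  expect_warning(fit <- icc_a1(m), "dropping 1 rater")
  expect_equal(fit$k_raters, 2L)
  m2 <- rbind(c(1, 2), c(2, 3), c(NA, NA))
  expect_message(fit2 <- icc_a1(m2), "dropping 1 subject")
  expect_equal(fit2$n_subjects, 2L)
  expect_error(icc_a1(cbind(c(1, 2), c(1, Inf))), "finite")
})

test_that("deleting one cell moves the estimate only slightly", {
  set.seed(22)
  sim <- simulate_ratings(sim_config(seed = 22, missing_rate_base = 0,
                                     missing_tail_boost = 0))
  m <- rating_matrix(sim$records, "total_sops")
  full <- icc_a1(m)
  expect_equal(full$method, "complete_anova")
  m[4, 2] <- NA
  part <- icc_a1(m)
  expect_equal(part$method, "incomplete_mom")
  expect_lt(abs(part$estimate - full$estimate), 0.05)
})

test_that("estimator is consistent for the latent ICC at large n", {
  set.seed(23)
  n <- 2000
  k <- 3
  s2s <- 1; s2r <- 0.3; s2e <- 0.7
  truth <- s2s / (s2s + s2r + s2e)
  s <- rnorm(n, 0, sqrt(s2s))
  r <- rnorm(k, 0, sqrt(s2r))
  m <- outer(s, r, "+") + matrix(rnorm(n * k, 0, sqrt(s2e)), n, k)
  expect_lt(abs(icc_a1(m)$estimate - truth), 0.02)
  # growing rater variance strictly lowers the large-sample estimate
  ests <- sapply(c(0.1, 0.5, 1.5), function(v) {
    r2 <- rnorm(k, 0, sqrt(v))
    icc_a1(outer(s, r2, "+") +
             matrix(rnorm(n * k, 0, sqrt(s2e)), n, k))$estimate
  })
  expect_true(all(diff(ests) < 0))
})

test_that("confidence intervals bracket the estimate and narrow with n", {
  set.seed(24)
  gen <- function(n) {
    s <- rnorm(n); r <- rnorm(3, 0, 0.3)
    outer(s, r, "+") + matrix(rnorm(n * 3, 0, 0.8), n, 3)
  }
  f10 <- icc_a1(gen(10))
  f100 <- icc_a1(gen(100))
  for (f in list(f10, f100)) {
    expect_lte(f$ci[1], f$estimate)
    expect_gte(f$ci[2], f$estimate)
  }
  expect_lt(diff(f100$ci), diff(f10$ci))
})

test_that("interpretation bands follow the published cut points", {
  expect_equal(interpret_icc(0.71), "good")
  expect_equal(interpret_icc(0.957), "excellent")
  expect_equal(interpret_icc(c(0.39, 0.40)), c("low", "fair"))
  expect_equal(interpret_icc(c(0.59, 0.60, 0.74, 0.75)),
               c("fair", "good", "good", "excellent"))
})

test_that("itemwise table covers all items, sorts, and reports validity", {
  cat19 <- sops_catalog()
  profiles <- list()
  set.seed(25)
  for (s in sprintf("S%02d", 1:10)) {
    profiles[[s]] <- stats::setNames(sample(0:6, 19, replace = TRUE),
                                     cat19$item_code)
  }
  recs <- identical_rater_records(profiles)
  tab <- itemwise_icc(recs)
  expect_equal(nrow(tab), 19L)
  expect_equal(tab$icc, rep(1, 19))  # identical raters agree perfectly
  expect_equal(tab$percent_valid, rep(100, 19))

  # 3 missing cells of 30 on one item -> 90% valid there
  recs2 <- recs
  drop_idx <- which(recs2$item_code == "N4")[1:3]
  recs2$rating[drop_idx] <- NA
  tab2 <- itemwise_icc(recs2)
  expect_equal(tab2$percent_valid[tab2$item == "N4"], 90.0)
  expect_equal(tab2$percent_valid[tab2$item == "P1"], 100.0)

  # descending order by default, catalog order on request
  sim <- simulate_ratings(sim_config(seed = 26))
  t_est <- itemwise_icc(sim$records)
  expect_true(all(diff(t_est$icc[!is.na(t_est$icc)]) <= 0))
  t_cat <- itemwise_icc(sim$records, sort_by = "catalog")
  expect_equal(t_cat$item, cat19$item_code)

  # an item rated by a single rater yields a reasoned missing row
  solo <- recs
  solo <- solo[!(solo$item_code == "G1" & solo$rater_id != "R1"), ]
  t_solo <- itemwise_icc(solo)
  g1 <- t_solo[t_solo$item == "G1", ]
  expect_true(is.na(g1$icc))
  expect_match(g1$note, "2 .*raters")
})

test_that("rater-bias-dominated items are less reliable than bias-free ones", {
  set.seed(27)
  diffs <- replicate(200, {
    s <- rnorm(18)
    e1 <- matrix(rnorm(18 * 3, 0, 0.5), 18, 3)
    e2 <- matrix(rnorm(18 * 3, 0, 0.5), 18, 3)
    bias <- rnorm(3, 0, 2)  # rater variance far above subject variance
    clean <- icc_a1(s + e1)$estimate
    biased <- icc_a1(sweep(s + e2, 2, -bias))$estimate
    clean - biased
  })
  expect_gt(mean(diffs), 0)
})

test_that("fit methods expose the model object coherently", {
  set.seed(28)
  m <- matrix(rnorm(12 * 3, 2), 12, 3)
  fit <- icc_a1(m)
  expect_named(coef(fit), "icc")
  ci <- confint(fit)
  expect_equal(as.vector(ci), fit$ci)
  wider <- confint(fit, level = 0.99)
  expect_lt(wider[1], ci[1])
  expect_gt(wider[2], ci[2])
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_equal(dim(sims[[1]]), c(12L, 3L))
  expect_output(print(fit), "ICC")
  expect_output(print(summary(fit)), "Variance components")
})
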