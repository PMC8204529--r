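test_that("the worked rule examples classify as the rules dictate", {
  expect_equal(classify_status(make_profile(p = c(3, 0, 0, 0, 0)))$category,
               "pos")
  expect_equal(classify_status(make_profile())$category, "npro")
  expect_equal(
    classify_status(make_profile(nd = c(3, 0, 0, 0, 0, 0, 0, 4, 0, 0)))$category,
    "neg_dis"
  )
  expect_equal(classify_status(make_profile(p = c(0, 0, 0, 6, 0)))$category,
               "acute_pos")
  expect_equal(
    classify_status(c(P1 = 4, N1 = 3, N2 = 6))$category,
    "pos_neg_dis"
  )
  # two qualifying neg/dis items are required, one is not enough
  expect_equal(
    classify_status(make_profile(nd = c(3, rep(0, 9))))$category,
    "npro"
  )
  # a 6 on a positive item dominates even a combined-qualifying profile
  expect_equal(
    classify_status(make_profile(p = c(6, 4, 0, 0, 0),
                                 nd = c(3, 3, 3, 0, 0, 0, 0, 0, 0, 0)))$category,
    "acute_pos"
  )
  expect_error(classify_status(c(G1 = 2)), "missing")
})

test_that("classification matches the rule oracle on a profile sweep", {
  set.seed(101)
  for (rep in 1:300) {
    p <- sample(0:6, 5, replace = TRUE)
    nd <- sample(0:6, 10, replace = TRUE)
    expect_equal(classify_status(make_profile(p = p, nd = nd))$category,
                 oracle_status(p, nd))
  }
})

test_that("general items never influence the category", {
  set.seed(7)
  for (rep in 1:50) {
    p <- sample(0:6, 5, replace = TRUE)
    nd <- sample(0:6, 10, replace = TRUE)
    g1 <- sample(0:6, 4, replace = TRUE)
    g2 <- sample(0:6, 4, replace = TRUE)
    expect_identical(
      classify_status(make_profile(p, nd, g1))$category,
      classify_status(make_profile(p, nd, g2))$category
    )
  }
})

test_that("category is invariant to permuting items within a subscale", {
  set.seed(8)
  for (rep in 1:50) {
    p <- sample(0:6, 5, replace = TRUE)
    nd <- sample(0:6, 10, replace = TRUE)
    expect_identical(
      classify_status(make_profile(p, nd))$category,
      classify_status(make_profile(sample(p), c(sample(nd[1:6]),
                                                sample(nd[7:10]))))$category
    )
  }
})

test_that("raising one item never lowers the severity ordinal", {
  set.seed(9)
  for (rep in 1:100) {
    p <- sample(0:6, 5, replace = TRUE)
    nd <- sample(0:6, 10, replace = TRUE)
    base <- classify_status(make_profile(p, nd))$ordinal_code
    i <- sample(15, 1)
    v <- c(p, nd)
    if (v[i] == 6) next
    v[i] <- v[i] + 1L
    bumped <- classify_status(make_profile(v[1:5], v[6:15]))$ordinal_code
    expect_gte(bumped, base)
  }
})

test_that("the complete flag tracks sensitivity to missing items", {
  # missing positive item could reach acute_pos -> incomplete
  st <- classify_status(make_profile(p = c(NA, 0, 0, 0, 0)))
  expect_false(st$complete)
  expect_equal(st$category, "npro")
  # already acute: no missing item can change the category
  st2 <- classify_status(make_profile(p = c(6, NA, 0, 0, 0)))
  expect_true(st2$complete)
  expect_equal(st2$category, "acute_pos")
  # fully scored profile is complete
  expect_true(classify_status(make_profile(p = c(4, 0, 0, 0, 0)))$complete)
})

test_that("status agreement flags unanimity and names off-raters", {
  st <- data.frame(
    subject_id = rep(c("S1", "S2"), each = 3),
    rater_id = rep(c("R1", "R2", "R3"), 2),
    category = c("npro", "npro", "npro", "pos", "pos", "acute_pos"),
    stringsAsFactors = FALSE
  )
  ag <- status_agreement(st)
  expect_equal(ag$table$unanimous, c(TRUE, FALSE))
  expect_match(ag$table$note[2], "R3")
  expect_match(ag$table$note[2], "pos")
  expect_equal(ag$unanimity, 0.5)
  both <- st
  both$category <- "neg_dis"
  expect_equal(status_agreement(both)$unanimity, 1.0)
})

test_that("consensus operators behave as documented", {
  prof <- make_profile(p = c(4, 0, 0, 0, 0))
  recs <- identical_rater_records(list(S1 = prof, S2 = make_profile()))
  for (mth in c("median_item", "majority_category")) {
    cs <- consensus_status(recs, method = mth)
    expect_equal(cs$category[cs$subject_id == "S1"], "pos")
    expect_equal(cs$category[cs$subject_id == "S2"], "npro")
  }
  # low median on even rater counts; strict majority of categories
  recs2 <- identical_rater_records(list(S1 = prof, S2 = make_profile()))
  recs2$rating[recs2$subject_id == "S1" & recs2$rater_id == "R1" &
                 recs2$item_code == "P1"] <- 2
  recs2$rating[recs2$subject_id == "S1" & recs2$rater_id == "R2" &
                 recs2$item_code == "P1"] <- 3
  recs2$rating[recs2$subject_id == "S1" & recs2$rater_id == "R3" &
                 recs2$item_code == "P1"] <- 3
  cs2 <- consensus_status(recs2, method = "median_item")
  expect_equal(cs2$category[cs2$subject_id == "S1"], "pos")  # median 3
  # even rater count: tie resolves to the lower middle value (2 -> npro)
  cs_even <- consensus_status(recs2[recs2$rater_id %in% c("R1", "R2"), ],
                              method = "median_item")
  expect_equal(cs_even$category[cs_even$subject_id == "S1"], "npro")
  # majority category with a 2:1 split
  cs3 <- consensus_status(recs2, method = "majority_category")
  expect_equal(cs3$category[cs3$subject_id == "S1"], "pos")
  expect_error(consensus_status(recs[recs$rater_id == "R1", ]),
               "at least 2 raters")
})

test_that("chr_split partitions on npro versus any subthreshold category", {
  st <- data.frame(
    subject_id = sprintf("S%02d", 1:18),
    category = rep(c("npro", "neg_dis", "pos", "pos_neg_dis"),
                   c(7, 6, 3, 2)),
    stringsAsFactors = FALSE
  )
  sp <- chr_split(st)
  expect_equal(sp$n_chr, 11L)
  expect_equal(sp$n_non_chr, 7L)
  expect_setequal(sp$non_chr, sprintf("S%02d", 1:7))
  small <- data.frame(subject_id = c("a", "b", "c"),
                      category = c("pos", "neg_dis", "npro"))
  sp2 <- chr_split(small)
  expect_setequal(sp2$chr, c("a", "b"))
  expect_setequal(sp2$non_chr, "c")
  expect_error(chr_split(rbind(small, small)), "one consensus status")
})
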