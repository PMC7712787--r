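test_that("Miller-Payne classification maps grades 4-5 to responders", {
  expect_true(classify_response(4))
  expect_true(classify_response(5))
  expect_false(classify_response(3))
  expect_identical(classify_response(c(1, 2, 3, 4, 5)),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_error(classify_response(6), "1..5")
  expect_error(classify_response(0), "1..5")
  expect_error(classify_response(2.5), "1..5")
})

test_that("AUC equals the brute-force pair-ordering oracle on small instances", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(4:12, 1L)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)   # both classes guaranteed
    # half the instances get heavy ties
    scores <- if (rep %% 2L) round(runif(n, 0, 4)) else rnorm(n)
    r <- roc_analysis(scores, labels)
    oracle <- brute_auc(scores, labels)
    expect_equal(r$auc, max(oracle, 1 - oracle))
    # orientation bookkeeping
    expect_identical(r$direction,
                     if (oracle >= 0.5) "responder_high" else "responder_low")
    # flipping labels and orientation leaves the AUC invariant
    r_flip <- roc_analysis(scores, !labels)
    expect_equal(r_flip$auc, r$auc)
  }
})

test_that("the Youden cutoff is maximal under an exhaustive threshold scan", {
  set.seed(32)
  for (rep in 1:25) {
    n <- sample(6:14, 1L)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.4)
    scores <- round(rnorm(n), 1)
    r <- roc_analysis(scores, labels)
    z <- if (r$direction == "responder_high") scores else -scores
    t_star <- if (r$direction == "responder_high") r$cutoff else -r$cutoff
    j_of <- function(t) mean(z[labels] >= t) + mean(z[!labels] < t) - 1
    # scan every midpoint and the observed values themselves
    cand <- sort(unique(c(z, (sort(unique(z))[-1] + rev(rev(sort(unique(z)))[-1])) / 2)))
    expect_true(all(j_of(t_star) >= vapply(cand, j_of, numeric(1)) - 1e-12))
    # reported sensitivity/specificity match the cutoff
    expect_equal(r$sensitivity, 100 * mean(z[labels] >= t_star))
    expect_equal(r$specificity, 100 * mean(z[!labels] < t_star))
  }
})

test_that("ROC handles separation, null data, missing scores and degenerate labels", {
  r <- roc_analysis(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_gt(r$cutoff, 3); expect_lt(r$cutoff, 10)

  set.seed(33)
  scores <- rnorm(600); labels <- rep(c(TRUE, FALSE), 300)
  null_r <- roc_analysis(scores, labels)
  expect_gt(0.5, null_r$ci_low)
  expect_lt(0.5, null_r$ci_high)

  # missing scores are dropped pairwise
  with_na <- roc_analysis(c(NA, 1, 2, 3, 4), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(with_na$n_pos + with_na$n_neg, 4L)

  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "at least one")
})

test_that("DeLong AUC and CI agree with the pROC reference", {
  set.seed(34)
  for (rep in 1:10) {
    n <- 40
    labels <- runif(n) > 0.6
    if (length(unique(labels)) < 2L) next
    scores <- rnorm(n) + 1.2 * labels
    r <- roc_analysis(scores, labels)
    pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    ci <- suppressWarnings(pROC::ci.auc(pr, method = "delong"))
    expect_equal(r$auc, max(as.numeric(pROC::auc(pr)), 1 - as.numeric(pROC::auc(pr))),
                 tolerance = 1e-12)
    if (r$direction == "responder_high") {
      expect_equal(r$ci_low, max(ci[1], 0), tolerance = 1e-9)
      expect_equal(r$ci_high, min(ci[3], 1), tolerance = 1e-9)
    }
  }
})

test_that("rank comparison matches exact enumeration and the normal approximation", {
  # no shift at all: p = 1 under exact enumeration
  expect_equal(rank_compare(c(2, 2, 2), c(2, 2, 2)), 1)
  # complete separation of 3 vs 3: 2 of the 20 assignments are as extreme
  expect_equal(rank_compare(c(1, 2, 3), c(10, 11, 12)), 0.1)

  set.seed(35)
  for (rep in 1:20) {
    m <- sample(2:6, 1L); n <- sample(2:6, 1L)
    x <- round(rnorm(m), 1); y <- round(rnorm(n, 0.5), 1)  # ties likely
    expect_equal(rank_compare(x, y), brute_mw_p(x, y))
  }

  # large samples: normal approximation close to wilcox.test without correction
  x <- rnorm(30); y <- rnorm(25, 0.4)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(rank_compare(x, y), ref$p.value, tolerance = 1e-10)

  expect_error(rank_compare(numeric(0), 1:3), "non-empty")
})

test_that("subgroup filtering keeps the right patients", {
  rec <- data.frame(patient_id = sprintf("P%02d", 1:6),
                    ER = c(TRUE, FALSE, FALSE, NA, FALSE, TRUE),
                    PR = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
                    HER2 = c(TRUE, FALSE, FALSE, FALSE, NA, FALSE))
  expect_identical(subgroup_filter(rec, "all"), rec)
  her2neg <- subgroup_filter(rec, "HER2_negative")
  expect_identical(her2neg$patient_id, c("P02", "P03", "P04", "P06"))
  tn <- subgroup_filter(rec, "triple_negative")
  expect_identical(tn$patient_id, "P02")
  expect_error(subgroup_filter(rec, "luminal"))

  # an empty subgroup makes the downstream ROC error cleanly
  none <- subgroup_filter(rec[c(1, 6), ], "triple_negative")
  expect_identical(nrow(none), 0L)
  expect_error(roc_analysis(none$ER, none$PR), "at least one")
})
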