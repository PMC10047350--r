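test_that("midrank AUC matches small hand-enumerated cases", {
  expect_equal(roc_auc(c(4, 5, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(roc_auc(c(2, 2, 2, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "undefined")
})

test_that("midrank AUC equals the brute-force concordant-pair oracle", {
  set.seed(91)
  for (trial in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(0:12, n, replace = TRUE)   # heavy ties on purpose
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels), auc_brute_force(scores, labels))
  }
})

test_that("orientation flip complements the AUC when there are no ties", {
  set.seed(14)
  for (trial in 1:25) {
    n <- sample(6:40, 1)
    scores <- rnorm(n)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels, "lower_is_worse"),
                 1 - roc_auc(scores, labels, "higher_is_worse"))
  }
})

test_that("DeLong interval brackets the AUC and degenerates at separation", {
  perfect <- roc_auc_ci(c(4, 5, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$se, 0)
  expect_equal(c(perfect$lo, perfect$hi), c(1, 1))
  ci <- roc_auc_ci(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(ci$lo <= 0.75 && ci$hi >= 0.75)
})

test_that("DeLong interval agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  cohort <- synthetic_cohort(300, seed = 21)
  sc <- score_cohort(cohort)
  keep <- !is.na(sc$gbs)
  ours <- roc_auc_ci(sc$gbs[keep], sc$outcome_death[keep])
  ref <- pROC::ci.auc(pROC::roc(sc$outcome_death[keep], sc$gbs[keep],
                                direction = "<", quiet = TRUE),
                      method = "delong")
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ours$lo, as.numeric(ref[1]), tolerance = 1e-10)
  expect_equal(ours$hi, as.numeric(ref[3]), tolerance = 1e-10)
})

test_that("DeLong interval is close to a bootstrap percentile interval", {
  cohort <- synthetic_cohort(200, seed = 8)
  sc <- score_cohort(cohort)
  keep <- !is.na(sc$inbs)
  dl <- roc_auc_ci(sc$inbs[keep], sc$outcome_death[keep])
  bt <- roc_auc_ci_boot(sc$inbs[keep], sc$outcome_death[keep],
                        reps = 2000, seed = 1234)
  expect_lt(abs(dl$lo - bt$lo), 0.02)
  expect_lt(abs(dl$hi - bt$hi), 0.02)
})

test_that("Youden cutoff maximises J and breaks ties toward sensitivity", {
  roc <- roc_curve(c(4, 5, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  cut <- youden_cutoff(roc)
  expect_equal(cut$cutoff, 4)
  expect_equal(cut$youden_j, 1)

  roc <- roc_curve(c(2, 5, 1, 3), c(TRUE, TRUE, FALSE, FALSE))
  cut <- youden_cutoff(roc)
  expect_equal(cut$youden_j, 0.5)
  expect_equal(cut$cutoff, 2)   # the tie at threshold 5 is not chosen

  roc <- roc_curve(c(2, 2, 2, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(youden_cutoff(roc)$youden_j, 0)
})

test_that("ROC curves respect their structural invariants", {
  cohort <- synthetic_cohort(150, seed = 13)
  sc <- score_cohort(cohort)
  keep <- !is.na(sc$gbs)
  roc <- roc_curve(sc$gbs[keep], sc$outcome_death[keep])
  expect_true(all(diff(roc$sensitivity) <= 1e-12))
  expect_true(all(diff(roc$specificity) >= -1e-12))
  auc <- attr(roc, "auc")
  ci <- attr(roc, "auc_ci")
  expect_true(ci[1] <= auc && auc <= ci[2])
  # lower-is-worse curve reports cutoffs on the original scale
  keep_t <- !is.na(sc$t_score)
  roc_t <- roc_curve(sc$t_score[keep_t], sc$outcome_death[keep_t],
                     "lower_is_worse")
  expect_true(all(youden_cutoff(roc_t)$cutoff %in% sc$t_score[keep_t]))
})

test_that("odds ratios reproduce the printed contingency analyses", {
  expect_equal(odds_ratio(contingency_2x2(75, 123, 114, 406)),
               2.1716, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(odds_ratio(contingency_2x2(18, 5, 11, 25)),
               8.1818, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(odds_ratio(contingency_2x2(1, 1, 1, 1)), 1,
               ignore_attr = TRUE)

  ci <- or_ci_woolf(contingency_2x2(18, 5, 11, 25))
  expect_equal(ci$lo, 2.4192, tolerance = 1e-3)
  expect_equal(ci$hi, 27.6707, tolerance = 1e-3)
  expect_equal(or_ci_woolf(contingency_2x2(75, 123, 121, 1507))$hi,
               10.6875, tolerance = 1e-3)
  sym <- or_ci_woolf(contingency_2x2(1, 1, 1, 1))
  expect_equal(log(sym$lo), -log(sym$hi))
})

test_that("Wald tests on the log odds ratio reproduce the printed p-values", {
  expect_equal(or_wald_test(contingency_2x2(21, 42, 36, 76))$p, 0.8719,
               tolerance = 1e-3)
  expect_equal(or_wald_test(contingency_2x2(39, 47, 36, 76))$p, 0.0586,
               tolerance = 1e-3)
  even <- or_wald_test(contingency_2x2(10, 10, 10, 10))
  expect_equal(even$z, 0)
  expect_equal(even$p, 1)
})

test_that("odds-ratio identities and interval behaviour hold", {
  set.seed(6)
  for (trial in 1:40) {
    cells <- sample(1:60, 4, replace = TRUE)
    t1 <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    t2 <- contingency_2x2(cells[2], cells[1], cells[4], cells[3])
    expect_equal(odds_ratio(t1) * odds_ratio(t2), 1, ignore_attr = TRUE)
    ci <- or_ci_woolf(t1)
    expect_true(ci$lo <= ci$or && ci$or <= ci$hi)
    ci10 <- or_ci_woolf(contingency_2x2(cells[1] * 10, cells[2] * 10,
                                        cells[3] * 10, cells[4] * 10))
    expect_lt(log(ci10$hi / ci10$lo), log(ci$hi / ci$lo))
  }
  # zero cell triggers the flagged Haldane correction
  h <- or_ci_woolf(contingency_2x2(5, 0, 3, 7))
  expect_true(h$haldane)
  expect_true(is.finite(h$or) && is.finite(h$hi))
})

test_that("chi-square and Fisher match hand-computed values", {
  cs <- chi_square_2x2(contingency_2x2(36, 76, 39, 47))
  expect_equal(cs$statistic, 198 * (36 * 47 - 76 * 39)^2 /
                 (112 * 86 * 75 * 123), tolerance = 1e-12)
  expect_equal(cs$statistic, 3.606, tolerance = 1e-3)
  prop <- chi_square_2x2(contingency_2x2(10, 20, 30, 60))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)
  expect_lt(chi_square_2x2(contingency_2x2(10, 0, 0, 10))$p, 0.001)
  expect_error(chi_square_2x2(contingency_2x2(0, 0, 5, 5)), "degenerate")

  expect_equal(fisher_exact(contingency_2x2(1, 1, 1, 1)), 1)
  expect_equal(fisher_exact(contingency_2x2(5, 0, 0, 5)), 2 / 252,
               tolerance = 1e-10)
})

test_that("Mann-Whitney wrapper returns the exact small-sample p", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$u, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-10)
  same <- mann_whitney(1:10, 1:10)
  expect_equal(same$u, 50)
  # p decreases with the location shift
  set.seed(2)
  a <- rnorm(100)
  ps <- vapply(c(0.2, 0.6, 1.2), function(d) {
    mann_whitney(a, rnorm(100, d))$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Swets bands label AUC values as published", {
  expect_equal(swets_category(0.844), "moderately_accurate")
  expect_equal(swets_category(0.5), "non_informative")
  expect_equal(swets_category(0.563), "less_accurate")
  expect_equal(swets_category(c(0.7, 0.9, 1)),
               c("moderately_accurate", "highly_accurate", "perfect"))
  expect_error(swets_category(1.2), "0, 1")
})
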