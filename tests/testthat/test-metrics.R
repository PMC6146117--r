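test_that("AUC follows the Mann-Whitney definition with half-credit ties", {
  expect_identical(auc(c(0.9, 0.1), c(TRUE, FALSE)), 1)
  expect_identical(auc(c(0.8, 0.6, 0.4, 0.2), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  expect_identical(auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auc(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
})

test_that("AUC equals the brute-force pairwise oracle on random inputs", {
  set.seed(101)
  for (k in 1:60) {
    n <- sample(5:120, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(labels) || all(labels)) next
    expect_equal(auc(scores, labels), auc_pairwise(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("binarization uses the score >= threshold convention", {
  ct <- binarize(c(0.5, 0.49), c(TRUE, TRUE), threshold = 0.5)
  expect_identical(ct$tp, 1L)
  expect_identical(ct$fn, 1L)
  all_pos <- binarize(rep(1, 5), rep(TRUE, 5))
  expect_identical(all_pos$tp, 5L)
  zero_thr <- binarize(c(0, 0.2, 0.9), c(TRUE, FALSE, TRUE), threshold = 0)
  expect_identical(zero_thr$tn, 0L)
  expect_identical(zero_thr$fp, 1L)
})

test_that("binary metrics match independent closed-form arithmetic", {
  perfect <- binary_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_identical(perfect[c("mcc", "f1", "error_rate")],
                   list(mcc = 1, f1 = 1, error_rate = 0))
  unit <- binary_metrics(list(tp = 1, fp = 1, tn = 1, fn = 1))
  expect_identical(unit$mcc, 0)
  expect_identical(unit$f1, 0.5)
  expect_identical(unit$error_rate, 0.5)
  # hand-computed oracle for tp=90, fn=10, fp=5, tn=95
  m <- binary_metrics(list(tp = 90, fp = 5, tn = 95, fn = 10))
  expect_equal(m$precision, 90 / 95, tolerance = 1e-12)
  expect_equal(m$recall, 90 / 100, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (90 / 95) * 0.9 / ((90 / 95) + 0.9), tolerance = 1e-12)
  expect_equal(m$mcc, (90 * 95 - 5 * 10) / sqrt(95 * 100 * 100 * 105),
               tolerance = 1e-12)
  expect_equal(m$error_rate, 15 / 200, tolerance = 1e-12)
  # zero-marginal convention
  expect_identical(binary_metrics(list(tp = 0, fp = 0, tn = 10, fn = 5))$mcc, 0)
})

test_that("MCC is symmetric under class swap while F1 is not", {
  a <- binary_metrics(list(tp = 80, fp = 10, tn = 40, fn = 5))
  b <- binary_metrics(list(tp = 40, fp = 5, tn = 80, fn = 10))  # swapped roles
  expect_equal(a$mcc, b$mcc, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$f1, b$f1)))
})

test_that("Brier score matches its closed forms", {
  expect_identical(brier(c(1, 0, 1), c(TRUE, FALSE, TRUE)), 0)
  expect_identical(brier(rep(0.5, 8), rep(c(TRUE, FALSE), 4)), 0.25)
  expect_equal(brier(c(0.8, 0.3), c(TRUE, FALSE)), 0.065, tolerance = 1e-12)
  # constant predictor p on prevalence pi scores pi(1-p)^2 + (1-pi)p^2
  y <- rep(c(TRUE, FALSE), times = c(13, 7))
  p <- 0.3
  pi_ <- mean(y)
  expect_equal(brier(rep(p, 20), y), pi_ * (1 - p)^2 + (1 - pi_) * p^2,
               tolerance = 1e-12)
  expect_error(brier(numeric(0), logical(0)), "empty")
})

test_that("calibration curves partition [0,1] and conserve counts", {
  scores <- c(0.975, 0.981, 0.999, 1.0)
  cc <- calibration_curve(scores, rep(TRUE, 4))
  expect_identical(nrow(cc), 20L)
  expect_identical(sum(cc$n), 4L)
  top <- cc[cc$n > 0, ]
  expect_identical(nrow(top), 1L)
  expect_identical(top$prop_positive, 1)
  set.seed(3)
  s2 <- runif(500); y2 <- runif(500) < s2
  cc2 <- calibration_curve(s2, y2, bin_width = 0.1)
  expect_identical(sum(cc2$n), 500L)
  expect_error(calibration_curve(s2, y2, bin_width = 0.3), "divide 1")
})

test_that("calibration adjusted R-squared matches the regression formula", {
  curve <- data.frame(lower = 0:4 / 5, upper = 1:5 / 5, n = c(10, 20, 30, 20, 10),
                      mean_score = c(0.1, 0.3, 0.5, 0.7, 0.9),
                      prop_positive = c(0.12, 0.25, 0.55, 0.72, 0.88))
  r2 <- cor(curve$mean_score, curve$prop_positive)^2
  adj <- 1 - (1 - r2) * (5 - 1) / (5 - 2)
  expect_equal(calibration_adjusted_r2(curve), adj, tolerance = 1e-12)
  # perfect calibration -> 1
  perf <- transform(curve, prop_positive = mean_score)
  expect_equal(suppressWarnings(calibration_adjusted_r2(perf)), 1,
               tolerance = 1e-12)
  # flat proportions carry no explanatory power
  flat <- transform(curve, prop_positive = 0.6)
  expect_lte(calibration_adjusted_r2(flat), 0)
  expect_error(calibration_adjusted_r2(curve[1:2, ]), "3 populated")
})

test_that("score histograms are per-class percentages summing to 100", {
  scores <- c(0.99, 0.98, 0.97, 0.02, 0.5)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  h <- score_histogram(scores, labels)
  expect_equal(sum(h$pct_positive), 100, tolerance = 1e-9)
  expect_equal(sum(h$pct_negative), 100, tolerance = 1e-9)
  expect_equal(h$pct_positive[20], 100, tolerance = 1e-9)
})

test_that("calibration error is zero for self-consistent scores and detects bias", {
  s <- seq(0.01, 0.99, length.out = 200)
  expect_equal(calibration_error(s, s), 0, tolerance = 1e-12)
  expect_gt(calibration_error(pmin(s + 0.2, 1), s), 0.1)
})

test_that("extreme-disagreement review agreement matches the published table", {
  tab <- agreement_table(low = c(2, 97, 1), high = c(50, 41, 9))
  st <- agreement_stats(tab)
  expect_equal(st$low_agreement_pct, 97.0, tolerance = 1e-12)
  expect_equal(st$high_agreement_pct, 50.0, tolerance = 1e-12)
  expect_equal(st$overall_agreement_pct, 73.5, tolerance = 1e-12)
  expect_error(agreement_stats(agreement_table(c(0, 0, 0), c(1, 1, 1))),
               "stratum")
})

test_that("full evaluation reports stay within their documented bounds", {
  set.seed(77)
  s <- runif(300); y <- runif(300) < s
  rep_ <- evaluate_scores(s, y)
  expect_true(rep_$auc >= 0 && rep_$auc <= 1)
  expect_true(rep_$mcc >= -1 && rep_$mcc <= 1)
  expect_true(all(unlist(rep_[c("f1", "recall", "precision", "brier",
                                "error_rate")]) >= 0))
  expect_true(all(unlist(rep_[c("f1", "recall", "precision", "brier",
                                "error_rate")]) <= 1))
  expect_identical(rep_$n, 300L)
})
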