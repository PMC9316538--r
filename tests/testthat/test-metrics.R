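test_that("confusion metrics reproduce hand arithmetic", {
  c1 <- list(TP = 37, FP = 4, FN = 4, TN = 2113)
  expect_equal(round(fdr(c1), 4), 0.9024)
  expect_equal(far(list(TP = 0, FP = 0, FN = 0, TN = 10)), 0)
  c2 <- list(TP = 2, FP = 1, FN = 1, TN = 6)
  expect_equal(precision(c2), 2 / 3)
  expect_equal(fdr(c2), 2 / 3)
  expect_equal(far(c2), 1 / 7)
  expect_equal(accuracy(c2), 8 / 10)
})

test_that("zero denominators flag the metric as undefined, never 0", {
  c0 <- list(TP = 0, FP = 0, FN = 3, TN = 7)
  expect_warning(p <- precision(c0), "undefined")
  expect_true(is.na(p))
  expect_warning(f <- far(list(TP = 1, FP = 0, FN = 0, TN = 0)), "undefined")
  expect_true(is.na(f))
})

test_that("detection and alarm rates complement their error rates", {
  set.seed(17)
  for (i in 1:20) {
    cts <- as.list(stats::setNames(sample(1:30, 4, TRUE),
                                   c("TP", "FP", "FN", "TN")))
    expect_equal(fdr(cts) + cts$FN / (cts$TP + cts$FN), 1)
    expect_equal(far(cts) + cts$TN / (cts$FP + cts$TN), 1)
  }
})

test_that("confusion_at_k matches exhaustive tabulation and conserves counts", {
  # the milk-study regime: 37 of the 41 failures inside the top-41
  set.seed(23)
  scores <- sort(runif(2158), decreasing = TRUE)
  unq <- rep(FALSE, 2158)
  unq[c(1:37, 49:52)] <- TRUE
  ct <- confusion_at_k(scores, unq, k = 41)
  expect_equal(ct[c("TP", "FP", "FN", "TN")],
               list(TP = 37L, FP = 4L, FN = 4L, TN = 2113L),
               ignore_attr = TRUE)

  # perfect ranking at k = U
  ct2 <- confusion_at_k(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE), k = 2)
  expect_equal(ct2$TP, 2); expect_equal(ct2$FP, 0); expect_equal(ct2$FN, 0)

  # random instances vs brute-force tabulation, with tie-prone scores
  for (i in 1:25) {
    n <- 30
    s <- sample(round(runif(n), 1))
    u <- runif(n) < 0.3
    k <- sample(1:n, 1)
    got <- confusion_at_k(s, u, k)
    want <- oracle_confusion(s, u, k)
    expect_equal(got[c("TP", "FP", "FN", "TN")], want, ignore_attr = TRUE)
    expect_equal(got$TP + got$FN, sum(u))
    expect_equal(got$FP + got$TN, sum(!u))
  }
})

test_that("auc equals all-pairs enumeration and has its invariances", {
  # perfect separation and the all-tie case
  expect_equal(auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(rep(2, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)),
               0.5)

  # 8 mixed scores vs enumeration
  s <- c(0.3, 0.9, 0.2, 0.9, 0.5, 0.1, 0.7, 0.5)
  u <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(auc(s, u), oracle_auc(s, u))

  # monotone-transform invariance and score-negation complement (no ties)
  set.seed(19)
  s2 <- runif(30); u2 <- runif(30) < 0.25
  if (!any(u2)) u2[1] <- TRUE
  expect_equal(auc(exp(3 * s2), u2), auc(s2, u2))
  expect_equal(auc(s2, u2) + auc(-s2, u2), 1)

  expect_warning(a <- auc(1:4, rep(FALSE, 4)), "empty")
  expect_true(is.na(a))
})

test_that("metrics_report assembles the five metrics under the top-k rule", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  u <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  rep <- metrics_report(s, u)          # k defaults to U = 2
  expect_equal(rep$counts$TP, 1)
  expect_equal(rep$fdr, 0.5)
  expect_equal(rep$far, 0.25)
  expect_equal(rep$accuracy, 4 / 6)
  expect_equal(rep$auc, auc(s, u))
  expect_true(all(vapply(rep[c("precision", "fdr", "far", "auc",
                               "accuracy")], function(v)
    v >= 0 && v <= 1, logical(1))))
})

test_that("level t-tests match the closed-form Welch statistic", {
  scores <- c(rnorm(40), rnorm(15, mean = 6))
  lev <- c(rep(0L, 40), rep(3L, 15))
  out <- level_ttest(scores, lev, pairs = list(c(0, 3)), n_per_level = 30,
                     seed = 5)
  # replay the seeded resampling and apply the Welch formula by hand
  set.seed(5)
  a <- sample(scores[lev == 0L], 30, replace = TRUE)
  b <- sample(scores[lev == 3L], 30, replace = TRUE)
  se <- sqrt(var(a) / 30 + var(b) / 30)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 30)^2 / 29 + (var(b) / 30)^2 / 29)
  expect_equal(out$t, t_hand)
  expect_equal(out$p_value, 2 * pt(-abs(t_hand), df_hand))
  # gross separation is significant; p is a valid probability
  expect_lt(out$p_value, 0.05)
  expect_true(out$p_value >= 0 && out$p_value <= 1)
})

test_that("level t-tests cover the standard pairs and skip empty pools", {
  set.seed(27)
  scores <- c(rnorm(60), rnorm(10, 3), rnorm(8, 5), rnorm(12, 9))
  lev <- rep(c(0L, 1L, 2L, 3L), c(60, 10, 8, 12))
  out <- level_ttest(scores, lev, seed = 2)
  expect_equal(nrow(out), 5)
  expect_equal(out$level_a, c(0, 1, 2, 0, 1))
  expect_equal(out$level_b, c(3, 3, 3, 1, 2))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  # drop level 1 entirely: each of its three pairs is skipped with a warning
  keep <- lev != 1L
  w <- capture_warnings(out2 <- level_ttest(scores[keep], lev[keep],
                                            seed = 2))
  expect_length(w, 3)
  expect_match(w, "skipped", all = TRUE)
  expect_equal(nrow(out2), 2)
})
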