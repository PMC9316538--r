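#' Confusion counts under the top-k prediction rule
#'
#' The unsupervised screen predicts "unsafe" for the k samples with the
#' largest anomaly scores (descending ranking with the package-wide
#' index tie-break) and "safe" for the rest; the counts are tabulated
#' against the ground-truth qualification labels with unqualified/unsafe as
#' the positive class.
#'
#' @param scores Numeric score vector.
#' @param labels Qualification labels (see [find_thresholds()] for accepted
#'   forms).
#' @param k Number of samples predicted unsafe, `1 <= k <= n`. Defaults to
#'   the ground-truth unqualified count.
#' @return An object of class `"confusion_counts"`: list with `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion_at_k <- function(scores, labels, k = NULL) {
  unq <- .as_unqualified(labels, length(scores))
  n <- length(scores)
  if (is.null(k)) k <- sum(unq)
  k <- as.integer(k)
  if (k < 1 || k > n) stop("k must lie in 1..n")
  ord <- rank_scores(scores)
  pred <- logical(n)
  pred[ord[seq_len(k)]] <- TRUE
  structure(list(TP = sum(pred & unq), FP = sum(pred & !unq),
                 FN = sum(!pred & unq), TN = sum(!pred & !unq)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts (positive = unsafe):\n")
  cat("  TP =", x$TP, " FP =", x$FP, " FN =", x$FN, " TN =", x$TN, "\n")
  invisible(x)
}

#' Confusion-derived screening metrics
#'
#' * `precision(c) = TP / (TP + FP)` -- inspection accuracy: the fraction
#'   of flagged samples that are truly unsafe;
#' * `fdr(c) = TP / (TP + FN)` -- fault detection rate (inspection
#'   completion rate): the fraction of truly unsafe samples recovered;
#' * `far(c) = FP / (FP + TN)` -- false alarm rate: the fraction of safe
#'   samples flagged unsafe by mistake;
#' * `accuracy(c) = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' A zero denominator makes the metric undefined and returns `NA` with a
#' warning (never silently 0).
#'
#' @param counts A `"confusion_counts"` object (or a list with `TP`, `FP`,
#'   `FN`, `TN`).
#' @return A number in `[0, 1]`, or `NA` if undefined.
#' @examples
#' fdr(list(TP = 37, FP = 4, FN = 4, TN = 2113))  # 0.9024 to 4 d.p.
#' @export
precision <- function(counts) .ratio(counts$TP, counts$TP + counts$FP,
                                     "precision")

#' @rdname precision
#' @export
fdr <- function(counts) .ratio(counts$TP, counts$TP + counts$FN, "fdr")

#' @rdname precision
#' @export
far <- function(counts) .ratio(counts$FP, counts$FP + counts$TN, "far")

#' @rdname precision
#' @export
accuracy <- function(counts)
  .ratio(counts$TP + counts$TN,
         counts$TP + counts$TN + counts$FP + counts$FN, "accuracy")

.ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined: zero denominator")
    return(NA_real_)
  }
  num / den
}

#' Pairwise ranking AUC
#'
#' The probability that a randomly drawn unsafe sample receives a higher
#' anomaly score than a randomly drawn safe sample, with ties counting
#' one half -- the Mann-Whitney formulation of the area under the ROC
#' curve. Computed from ranks; equal to brute-force enumeration over all
#' (unsafe, safe) pairs.
#'
#' @param scores Numeric score vector.
#' @param labels Qualification labels.
#' @return A number in `[0, 1]`, or `NA` with a warning if either class is
#'   empty.
#' @export
auc <- function(scores, labels) {
  unq <- .as_unqualified(labels, length(scores))
  n_pos <- sum(unq); n_neg <- sum(!unq)
  if (n_pos == 0 || n_neg == 0) {
    warning("auc undefined: one class is empty")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[unq]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full metrics report for one scorer run
#'
#' Applies the top-k rule (`k` defaulting to the ground-truth unsafe
#' count), tabulates the confusion counts and derives the five screening
#' metrics plus the wall-clock runtime when supplied.
#'
#' @param scores Numeric score vector.
#' @param labels Qualification labels.
#' @param k Top-k cutoff (default: the unqualified count).
#' @param runtime Optional elapsed seconds, recorded as-is (informational).
#' @return An object of class `"metrics_report"`: list with `counts` and
#'   numeric `precision`, `fdr`, `far`, `auc`, `accuracy`,
#'   `runtime_seconds`.
#' @export
metrics_report <- function(scores, labels, k = NULL, runtime = NA_real_) {
  counts <- confusion_at_k(scores, labels, k)
  structure(list(counts = counts,
                 precision = precision(counts),
                 fdr = fdr(counts),
                 far = far(counts),
                 auc = auc(scores, labels),
                 accuracy = accuracy(counts),
                 runtime_seconds = runtime),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Screening metrics (top-", x$counts$TP + x$counts$FP,
      " rule):\n", sep = "")
  v <- c(precision = x$precision, FDR = x$fdr, FAR = x$far,
         AUC = x$auc, accuracy = x$accuracy)
  print(round(v, digits))
  if (is.finite(x$runtime_seconds))
    cat("runtime:", format(x$runtime_seconds, digits = 3), "s\n")
  invisible(x)
}

#' Resampled t-tests between risk-level score pools
#'
#' Draws `n_per_level` scores with replacement from each risk level's score
#' pool and compares the level pairs `{0,3}, {1,3}, {2,3}, {0,1}, {1,2}`
#' with a two-sample t-test (Welch by default), reporting the two-sided
#' p-value. A significant difference between level 3 and the lower levels
#' supports the validity of the stratification; no correction for multiple
#' comparisons is applied (raw p-values are reported).
#'
#' @param scores Numeric score vector.
#' @param levels A `"risk_levels"` vector (or plain integers in `0:3`).
#' @param pairs List of length-2 integer vectors of levels to compare.
#' @param n_per_level Resample size per pool (default 100).
#' @param seed Integer seed for the resampling.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return A data frame with columns `level_a`, `level_b`, `t`, `p_value`.
#'   Pairs with an empty pool are skipped with a warning.
#' @export
level_ttest <- function(scores, levels,
                        pairs = list(c(0, 3), c(1, 3), c(2, 3),
                                     c(0, 1), c(1, 2)),
                        n_per_level = 100, seed = 1, var_equal = FALSE) {
  lev <- as.integer(unclass(levels))
  stopifnot(length(lev) == length(scores))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  rows <- lapply(pairs, function(pr) {
    pool_a <- scores[lev == pr[1]]
    pool_b <- scores[lev == pr[2]]
    if (!length(pool_a) || !length(pool_b)) {
      warning("level pair {", pr[1], ",", pr[2],
              "} skipped: empty score pool")
      return(NULL)
    }
    a <- sample(pool_a, n_per_level, replace = TRUE)
    b <- sample(pool_b, n_per_level, replace = TRUE)
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(level_a = pr[1], level_b = pr[2],
               t = unname(tt$statistic), p_value = tt$p.value)
  })
  do.call(rbind, rows)
}
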