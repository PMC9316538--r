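#' Rank samples by descending risk score
#'
#' Returns the permutation that orders scores from highest to lowest risk.
#' Ties are broken by the original row index (ascending), so the ranking is
#' stable and reproducible.
#'
#' @param scores Numeric vector of anomaly scores.
#' @return Integer permutation: `scores[rank_scores(scores)]` is
#'   non-increasing.
#' @export
rank_scores <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  order(-scores, seq_along(scores))
}

#' Rank-derived early-warning score thresholds
#'
#' With `U` unqualified samples in a labelled batch, two score cutoffs
#' emerge from the descending ranking: the score at rank `U` (the band the
#' unqualified samples would fill under a perfect ranking) and the score at
#' rank `n*`, where `n*` is the smallest n such that the top-n scores
#' contain every unqualified sample. In the motivating milk study U = 41
#' and all failures were recovered within the top 52, giving the thresholds
#' r_top-41 and r_top-52.
#'
#' @param scores Numeric score vector.
#' @param labels A `"qualification"` object (or a character/logical vector
#'   marking unqualified samples).
#' @return An object of class `"threshold_pair"`: list with `r_at_U`,
#'   `r_at_nstar`, `U`, `n_star`.
#' @examples
#' th <- find_thresholds(c(0.9, 0.8, 0.7, 0.6, 0.5),
#'                       c(TRUE, FALSE, FALSE, TRUE, FALSE))
#' th$n_star  # 4: the lowest-ranked failure sits at rank 4
#' @export
find_thresholds <- function(scores, labels) {
  unq <- .as_unqualified(labels, length(scores))
  U <- sum(unq)
  if (U == 0)
    stop("no unqualified samples: thresholds undefined")
  ord <- rank_scores(scores)
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(ord)
  n_star <- max(ranks[unq])
  structure(list(r_at_U = scores[ord[U]],
                 r_at_nstar = scores[ord[n_star]],
                 U = U, n_star = n_star),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat("Early-warning thresholds: U =", x$U, "unqualified, n* =", x$n_star,
      "\n")
  cat("  score at rank U  (medium-risk cutoff):",
      format(x$r_at_U, digits = 6), "\n")
  cat("  score at rank n* (low-risk cutoff):   ",
      format(x$r_at_nstar, digits = 6), "\n")
  invisible(x)
}

#' Assign four-level early-warning risk classes
#'
#' Unqualified samples are always high risk (level 3). Qualified samples
#' are banded by their anomaly score against the two rank-derived
#' thresholds: scores below the n*-rank cutoff are safe (0); scores inside
#' the top-n* band but below the top-U band are low risk (1); scores inside
#' the top-U band are medium risk (2). Band edges are lower-edge inclusive:
#'
#' * level 0: `score <  r_at_nstar`
#' * level 1: `r_at_nstar <= score < r_at_U`
#' * level 2: `score >= r_at_U`
#'
#' Thresholds normally come from [find_thresholds()] on the same batch;
#' frozen thresholds from a reference batch can be applied to score new
#' samples.
#'
#' @param scores Numeric score vector.
#' @param labels Qualification labels for the same samples.
#' @param thresholds A `"threshold_pair"`.
#' @return An object of class `"risk_levels"`: integer vector in `0:3` with
#'   attribute `thresholds`.
#' @export
assign_levels <- function(scores, labels, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  unq <- .as_unqualified(labels, length(scores))
  lev <- integer(length(scores))
  q <- !unq
  lev[unq] <- 3L
  lev[q & scores >= thresholds$r_at_U] <- 2L
  lev[q & scores >= thresholds$r_at_nstar & scores < thresholds$r_at_U] <- 1L
  structure(lev, thresholds = thresholds, class = "risk_levels")
}

#' @export
print.risk_levels <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = 0:3,
                      labels = c("safe", "low", "medium", "high")))
  cat("Early-warning risk levels:\n")
  print(tab)
  invisible(x)
}

#' Write the per-sample risk classification
#'
#' Writes `sample_id,score,qualified,level` as CSV with the thresholds in a
#' JSON sidecar (`<path>.thresholds.json`).
#'
#' @param sample_id Character vector of identifiers.
#' @param scores Numeric score vector.
#' @param labels Qualification labels.
#' @param levels A `"risk_levels"` vector from [assign_levels()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_risk_levels <- function(sample_id, scores, labels, levels, path) {
  unq <- .as_unqualified(labels, length(scores))
  df <- data.frame(sample_id = sample_id, score = scores,
                   qualified = !unq, level = as.integer(levels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  th <- attr(levels, "thresholds")
  if (!is.null(th))
    jsonlite::write_json(unclass(th), paste0(path, ".thresholds.json"),
                         digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# Coerce the accepted label representations to a logical "is unqualified"
# vector of length n.
.as_unqualified <- function(labels, n) {
  unq <- if (inherits(labels, "qualification")) {
    labels$labels == "unqualified"
  } else if (is.logical(labels)) {
    labels
  } else if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "unqualified"
  } else {
    stop("labels must be a qualification object, a logical vector or a ",
         "character vector of 'qualified'/'unqualified'")
  }
  if (length(unq) != n)
    stop("labels length (", length(unq), ") does not match scores (", n, ")")
  unq
}
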