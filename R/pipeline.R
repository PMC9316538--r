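#' End-to-end early-warning screen of an inspection batch
#'
#' Runs the full pipeline on one batch: qualification against the legal
#' limits, direction-aware normalization, auto-encoder anomaly scoring,
#' rank-threshold discovery and four-level risk classification. This is the
#' one-call interface; the individual stages are available as
#' [qualify()], [normalize_batch()], [risk_autoencoder()],
#' [find_thresholds()] and [assign_levels()].
#'
#' @param batch An [inspection_batch] (e.g. from [read_batch()] or
#'   [simulate_milk_batch()]).
#' @param model `"ae"` (default) or `"dae"`.
#' @param noise_sd Corruption SD when `model = "dae"` (default 0.3).
#' @param interval_absolute Passed to [normalize_batch()].
#' @param seed Seed for the model fit.
#' @param ... Further arguments to [risk_autoencoder()].
#' @return An object of class `"asrws"`: list with `batch`,
#'   `qualification`, `normalized`, `fit`, `scores`, `thresholds`,
#'   `levels`.
#' @examples
#' sim <- simulate_milk_batch(n = 150, contamination = 0.04, seed = 11)
#' screen <- asrws(sim$batch, epochs = 200)
#' screen
#' @export
asrws <- function(batch, model = c("ae", "dae"), noise_sd = 0.3,
                  interval_absolute = FALSE, seed = 1, ...) {
  stopifnot(inherits(batch, "inspection_batch"))
  model <- match.arg(model)
  qual <- qualify(batch)
  nb <- normalize_batch(batch, interval_absolute = interval_absolute)
  fit <- risk_autoencoder(nb,
                          noise_sd = if (model == "dae") noise_sd else 0,
                          seed = seed, ...)
  scores <- fit$scores
  thresholds <- find_thresholds(scores, qual)
  levels <- assign_levels(scores, qual, thresholds)
  structure(list(batch = batch, qualification = qual, normalized = nb,
                 fit = fit, scores = scores, thresholds = thresholds,
                 levels = levels),
            class = "asrws")
}

#' @export
print.asrws <- function(x, ...) {
  cat("Anomaly score-based risk early warning screen\n")
  n <- length(x$scores)
  U <- x$thresholds$U
  cat("  ", n, " samples, ", U, " unqualified (",
      format(100 * U / n, digits = 3), "%)\n", sep = "")
  cat("  thresholds: n* =", x$thresholds$n_star,
      " r_at_U =", format(x$thresholds$r_at_U, digits = 5),
      " r_at_n* =", format(x$thresholds$r_at_nstar, digits = 5), "\n")
  tab <- table(factor(unclass(x$levels), levels = 0:3,
                      labels = c("safe", "low", "medium", "high")))
  cat("  risk levels:", paste(names(tab), tab, sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' @export
summary.asrws <- function(object, ...) {
  rep <- metrics_report(object$scores, object$qualification)
  out <- list(screen = object, metrics = rep)
  class(out) <- "summary.asrws"
  out
}

#' @export
print.summary.asrws <- function(x, ...) {
  print(x$screen)
  cat("\nDetection of the unqualified class by the score ranking:\n")
  print(x$metrics)
  invisible(x)
}

#' @export
plot.asrws <- function(x, ...) {
  unq <- x$qualification$labels == "unqualified"
  graphics::plot(seq_along(x$scores), x$scores, log = "y",
                 pch = ifelse(unq, 17, 20),
                 col = ifelse(unq, "red", "grey40"),
                 xlab = "sample index",
                 ylab = "reconstruction error (log scale)",
                 main = "Early-warning scores", ...)
  graphics::abline(h = c(x$thresholds$r_at_U, x$thresholds$r_at_nstar),
                   lty = c(2, 3))
  graphics::legend("topright",
                   legend = c("unqualified", "qualified",
                              "medium-risk cutoff", "low-risk cutoff"),
                   pch = c(17, 20, NA, NA), lty = c(NA, NA, 2, 3),
                   col = c("red", "grey40", "black", "black"), cex = 0.8)
  invisible(x)
}
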