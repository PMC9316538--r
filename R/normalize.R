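#' Direction-aware min-max normalization
#'
#' Raw indicators live on incommensurable scales and point in different risk
#' directions: for a maximum-limit indicator a higher reading means higher
#' risk, for a minimum-limit indicator a higher reading means lower risk.
#' Normalization makes the columns dimensionless and aligns their direction
#' so that, for the one-sided indicators, a higher normalized value always
#' means higher risk. With per-column statistics (min_j, max_j, mean_j)
#' computed over the batch:
#'
#' * max-limit columns: `x* = (x - min) / (max - min)` (in `[0, 1]`);
#' * min-limit columns: `x* = 1 - (x - min) / (max - min)` (in `[0, 1]`);
#' * interval columns: `x* = (x - mean) / (max - min)` (signed, in
#'   `[-1, 1]`), or `|x - mean| / (max - min)` when
#'   `interval_absolute = TRUE` so that deviation to either side raises the
#'   value.
#'
#' Statistics default to the batch being transformed (transductive, the
#' single-batch usage); passing `stats` from a reference batch freezes them
#' so new samples can be transformed consistently.
#'
#' @param batch An [inspection_batch] with cleaned, complete values.
#' @param interval_absolute Use the absolute deviation form for interval
#'   indicators (default `FALSE`: signed, as the plain centred form).
#' @param stats Optional frozen `column_stats` data frame from a previous
#'   `normalize_batch()` result (columns `name`, `min`, `max`, `mean`).
#' @return An object of class `"normalized_batch"`: list with `values`
#'   (n x m numeric matrix), `column_stats`, `specs`, `sample_id`,
#'   `interval_absolute`.
#' @examples
#' sim <- simulate_milk_batch(n = 50, contamination = 0.04, seed = 1)
#' nb <- normalize_batch(sim$batch)
#' range(nb$values[, "protein"])
#' @export
normalize_batch <- function(batch, interval_absolute = FALSE, stats = NULL) {
  stopifnot(inherits(batch, "inspection_batch"))
  x <- batch$values
  if (anyNA(x)) stop("normalize needs complete values; missing cell found")
  specs <- batch$specs
  if (is.null(stats)) {
    stats <- data.frame(name = specs$name,
                        min = apply(x, 2, min),
                        max = apply(x, 2, max),
                        mean = colMeans(x),
                        stringsAsFactors = FALSE)
  } else {
    stats <- as.data.frame(stats)
    if (!identical(as.character(stats$name), specs$name))
      stop("frozen column stats do not match the batch's indicators")
  }
  const <- which(stats$max <= stats$min)
  if (length(const))
    stop("constant column (max = min): ",
         paste(stats$name[const], collapse = ", "),
         "; min-max transform undefined")
  out <- x
  for (j in seq_len(ncol(x))) {
    rng <- stats$max[j] - stats$min[j]
    mm <- (x[, j] - stats$min[j]) / rng
    out[, j] <- switch(specs$bound_kind[j],
      max_limit = mm,
      min_limit = 1 - mm,
      interval  = {
        d <- (x[, j] - stats$mean[j]) / rng
        if (interval_absolute) abs(d) else d
      })
  }
  rownames(stats) <- NULL
  structure(list(values = out, column_stats = stats, specs = specs,
                 sample_id = batch$sample_id,
                 interval_absolute = interval_absolute),
            class = "normalized_batch")
}

#' @export
print.normalized_batch <- function(x, ...) {
  cat("Normalized batch:", nrow(x$values), "samples x",
      ncol(x$values), "indicators\n")
  cat("Column statistics:\n")
  print(x$column_stats, row.names = FALSE)
  invisible(x)
}

#' @export
dim.normalized_batch <- function(x) dim(x$values)

#' Write a normalized matrix and its column statistics
#'
#' Writes the normalized values as CSV (header `sample_id,<indicators>`)
#' plus a JSON sidecar of the per-column min/max/mean used in the transform,
#' so the transform can be replayed on new samples.
#'
#' @param nb A `"normalized_batch"` from [normalize_batch()].
#' @param path Output CSV path; the sidecar is written to
#'   `<path>.stats.json`.
#' @return Invisibly, `path`.
#' @export
write_normalized <- function(nb, path) {
  stopifnot(inherits(nb, "normalized_batch"))
  df <- data.frame(sample_id = nb$sample_id, as.data.frame(nb$values),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(nb$column_stats, paste0(path, ".stats.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Corrupt a normalized batch with localized Gaussian noise
#'
#' Emulates partially missing or mis-recorded laboratory readings: a fixed
#' fraction of samples is selected (exactly `ceiling(sample_fraction * n)`
#' distinct rows) and, in each selected row, exactly one indicator receives
#' additive zero-mean Gaussian noise on the normalized scale. All other
#' cells are untouched.
#'
#' @param nb A `"normalized_batch"` (or a plain numeric matrix).
#' @param sample_fraction Fraction of samples to corrupt, in `[0, 1]`.
#' @param noise_sd Standard deviation of the perturbation on the normalized
#'   scale (default 0.3).
#' @param seed Integer seed for row/column selection and noise draws.
#' @return A list with `values` (corrupted matrix of the same shape) and
#'   `mask` (logical matrix, `TRUE` exactly at perturbed cells). If `nb`
#'   was a `"normalized_batch"`, `values` is returned inside a copy of it.
#' @export
inject_noise <- function(nb, sample_fraction, noise_sd = 0.3, seed = 1) {
  x <- if (inherits(nb, "normalized_batch")) nb$values else as.matrix(nb)
  if (!is.finite(sample_fraction) || sample_fraction < 0 ||
      sample_fraction > 1)
    stop("sample_fraction must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  n <- nrow(x); m <- ncol(x)
  mask <- matrix(FALSE, n, m, dimnames = dimnames(x))
  n_corrupt <- ceiling(sample_fraction * n)
  if (n_corrupt > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    rows <- sample.int(n, n_corrupt)
    cols <- sample.int(m, n_corrupt, replace = TRUE)
    eps <- stats::rnorm(n_corrupt, mean = 0, sd = noise_sd)
    x[cbind(rows, cols)] <- x[cbind(rows, cols)] + eps
    mask[cbind(rows, cols)] <- TRUE
  }
  if (inherits(nb, "normalized_batch")) {
    out <- nb
    out$values <- x
    list(values = out, mask = mask)
  } else {
    list(values = x, mask = mask)
  }
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
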