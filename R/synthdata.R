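#' Simulate a labelled sterilized-milk inspection batch
#'
#' Generates a synthetic batch emulating routine sterilized-milk inspection
#' against the GB 25190-2010 limits: six indicators (lactose, acidity,
#' nonfat milk solids, fat, protein, aflatoxin M1), a large majority of
#' qualified samples and a small planted set of out-of-specification
#' samples. In-specification values are drawn from per-indicator Gaussians
#' truncated to lie inside the legal limits (and plausible physical ranges),
#' centred near typical routine-testing readings. Each unqualified sample
#' violates exactly one indicator, drawn by pushing that indicator past its
#' limit by a uniform 5--30% of the limit's magnitude (for the acidity
#' interval, a side is chosen at random). The planted unqualified count is
#' exact: `round(n * contamination)` rows, so labels agree exactly with
#' [qualify()] on the generated batch.
#'
#' The defaults emulate the regime of a provincial milk-testing archive:
#' 2158 samples of which 41 (about 1.9%) fail at least one limit, inspection
#' dates spread uniformly over November 2013 to October 2021.
#'
#' @param n Number of samples (default 2158).
#' @param contamination Fraction of unqualified samples (default `41/2158`);
#'   `round(n * contamination)` must be at least 1.
#' @param seed Integer seed; the same seed reproduces the batch exactly.
#' @param means,sds Named numeric vectors of in-specification means and
#'   standard deviations on the raw scale (defaults below).
#' @param violation_range Length-2 numeric: the relative excursion past the
#'   limit for violated indicators (default `c(0.05, 0.30)`).
#' @return A list with `batch` (an [inspection_batch]) and `labels`
#'   (a `"qualification"` object matching `qualify(batch)`).
#' @examples
#' sim <- simulate_milk_batch(n = 100, contamination = 0.05, seed = 7)
#' table(sim$labels$labels)
#' @export
simulate_milk_batch <- function(n = 2158, contamination = 41 / 2158,
                                seed = 1,
                                means = NULL, sds = NULL,
                                violation_range = c(0.05, 0.30)) {
  specs <- milk_indicator_specs()
  defaults_mean <- c(lactose = 1.75, acidity = 12.1, nms = 8.8,
                     fat = 4.2, protein = 3.4, am1 = 0.3)
  defaults_sd <- c(lactose = 0.05, acidity = 0.20, nms = 0.15,
                   fat = 0.15, protein = 0.08, am1 = 0.08)
  names(defaults_mean) <- names(defaults_sd) <- specs$name
  if (!is.null(means)) defaults_mean[names(means)] <- means
  if (!is.null(sds)) defaults_sd[names(sds)] <- sds
  means <- defaults_mean; sds <- defaults_sd
  stopifnot(length(violation_range) == 2, violation_range[1] > 0,
            violation_range[2] >= violation_range[1])

  n <- as.integer(n)
  if (n < 1) stop("n must be positive")
  n_bad <- round(n * contamination)
  if (n_bad < 1)
    stop("contamination x n < 1: at least one unqualified sample is ",
         "required for threshold discovery")
  if (n_bad >= n) stop("contamination too large: no qualified samples left")

  # physical truncation ranges for in-spec draws (inside the legal limits)
  trunc_lo <- c(1.40, 11.0, 8.5, 3.7, 3.1, 0.02)
  trunc_hi <- c(2.00, 16.0, 9.5, 4.8, 3.8, 0.50)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  m <- nrow(specs)
  x <- matrix(NA_real_, n, m, dimnames = list(NULL, specs$name))
  for (j in seq_len(m))
    x[, j] <- .rtruncnorm(n, means[j], sds[j], trunc_lo[j], trunc_hi[j])

  bad_rows <- sort(sample.int(n, n_bad))
  bad_ind <- sample.int(m, n_bad, replace = TRUE)
  delta <- stats::runif(n_bad, violation_range[1], violation_range[2])
  side <- stats::runif(n_bad) < 0.5   # interval indicators: low vs high side
  for (i in seq_len(n_bad)) {
    j <- bad_ind[i]
    x[bad_rows[i], j] <- switch(specs$bound_kind[j],
      min_limit = specs$lo[j] * (1 - delta[i]),
      max_limit = specs$hi[j] * (1 + delta[i]),
      interval  = if (side[i]) specs$lo[j] * (1 - delta[i])
                  else specs$hi[j] * (1 + delta[i]))
  }

  day0 <- as.Date("2013-11-01"); day1 <- as.Date("2021-10-31")
  date <- sort(day0 + sample.int(as.integer(day1 - day0) + 1L, n,
                                 replace = TRUE) - 1L)
  sample_id <- paste0(format(date, "%Y%m%d"), "-", seq_len(n))

  batch <- inspection_batch(x, specs, sample_id = sample_id, date = date)
  labels <- qualify(batch)
  stopifnot(sum(labels$labels == "unqualified") == n_bad)
  list(batch = batch, labels = labels)
}

# Truncated Gaussian draws by inverse-CDF: deterministic given the RNG
# stream, no rejection loop.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}
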