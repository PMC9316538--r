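#' Scorer factories for benchmark experiments
#'
#' Each factory returns a scorer closure `function(x, seed)` mapping a
#' normalized value matrix to a per-sample anomaly score vector, suitable
#' for [run_benchmark()] and the robustness experiments. `scorer_ae()` and
#' `scorer_dae()` train an auto-encoder / denoising auto-encoder afresh per
#' call with the given seed; `scorer_knn()` and `scorer_kmeans()` wrap the
#' distance-based baselines (KNN ignores the seed -- it is deterministic).
#'
#' @param ... Passed through to [risk_autoencoder()] (architecture, epochs,
#'   learning rate, ...).
#' @param noise_sd Corruption SD of the DAE (default 0.3).
#' @param k Neighbour count for [knn_score()].
#' @param n_clusters Cluster count for [kmeans_score()].
#' @return A function `(x, seed) -> numeric scores`.
#' @export
scorer_ae <- function(...) {
  function(x, seed) risk_autoencoder(x, ..., seed = seed)$scores
}

#' @rdname scorer_ae
#' @export
scorer_dae <- function(noise_sd = 0.3, ...) {
  function(x, seed)
    risk_autoencoder(x, noise_sd = noise_sd, ..., seed = seed)$scores
}

#' @rdname scorer_ae
#' @export
scorer_knn <- function(k = 5) {
  function(x, seed) knn_score(x, k = k)
}

#' @rdname scorer_ae
#' @export
scorer_kmeans <- function(n_clusters = 8) {
  function(x, seed) kmeans_score(x, n_clusters = n_clusters, seed = seed)
}

.default_scorers <- function() {
  list(AE = scorer_ae(), DAE = scorer_dae(), KNN = scorer_knn(),
       `K-means` = scorer_kmeans())
}

#' Multi-run scorer benchmark
#'
#' Runs every scorer once per seed on the same labelled batch and reports
#' the per-scorer mean fault detection rate, false alarm rate, AUC and
#' accuracy under the top-k rule, plus the mean wall-clock time -- the
#' usual mean-over-five-random-initializations benchmark table. A failing
#' scorer yields an `NA` row (with a warning) without affecting the others.
#'
#' @param x A `"normalized_batch"` or numeric matrix.
#' @param labels Qualification labels for the rows of `x`.
#' @param scorers Named list of scorer closures (default: AE, DAE, KNN,
#'   K-means with package defaults).
#' @param seeds Integer vector of per-run seeds (default `1:5`).
#' @param k Top-k cutoff (default: ground-truth unqualified count).
#' @return A data frame with one row per scorer: `scorer`, `fdr`, `far`,
#'   `auc`, `accuracy`, `time_s`.
#' @export
run_benchmark <- function(x, labels, scorers = .default_scorers(),
                          seeds = 1:5, k = NULL) {
  if (inherits(x, "normalized_batch")) x <- x$values
  stopifnot(length(names(scorers)) == length(scorers))
  rows <- lapply(names(scorers), function(nm) {
    res <- lapply(seeds, function(s) {
      t0 <- proc.time()[["elapsed"]]
      sc <- tryCatch(scorers[[nm]](x, s), error = function(e) {
        warning("scorer '", nm, "' failed on seed ", s, ": ",
                conditionMessage(e))
        NULL
      })
      if (is.null(sc)) return(NULL)
      rep <- metrics_report(sc, labels, k = k,
                            runtime = proc.time()[["elapsed"]] - t0)
      c(fdr = rep$fdr, far = rep$far, auc = rep$auc,
        accuracy = rep$accuracy, time_s = rep$runtime_seconds)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res))
      return(data.frame(scorer = nm, fdr = NA_real_, far = NA_real_,
                        auc = NA_real_, accuracy = NA_real_,
                        time_s = NA_real_))
    m <- colMeans(do.call(rbind, res))
    data.frame(scorer = nm, fdr = m[["fdr"]], far = m[["far"]],
               auc = m[["auc"]], accuracy = m[["accuracy"]],
               time_s = m[["time_s"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Noise-ratio robustness experiment
#'
#' For each corruption fraction, a copy of the batch has
#' `ceiling(fraction * n)` samples corrupted (one indicator each, Gaussian
#' noise of SD `noise_sd` on the normalized scale), every scorer is
#' retrained/rescored on the corrupted values, and FDR/FAR against the
#' unchanged ground-truth labels are averaged over the seeds. The
#' fraction-0 rows coincide with the clean benchmark.
#'
#' @inheritParams run_benchmark
#' @param fractions Corruption fractions in `[0, 1]`
#'   (default `c(0, 0.03, 0.05, 0.10, 0.15)`).
#' @param noise_sd Corruption SD on the normalized scale (default 0.3).
#' @return A data frame with one row per scorer x fraction: `scorer`,
#'   `fraction`, `fdr`, `far`.
#' @export
run_noise_experiment <- function(x, labels,
                                 fractions = c(0, 0.03, 0.05, 0.10, 0.15),
                                 noise_sd = 0.3,
                                 scorers = .default_scorers(),
                                 seeds = 1:5, k = NULL) {
  if (inherits(x, "normalized_batch")) x <- x$values
  stopifnot(all(fractions >= 0 & fractions <= 1))
  rows <- list()
  for (fr in fractions) {
    per_seed <- lapply(seeds, function(s) {
      xs <- if (fr > 0)
        inject_noise(x, sample_fraction = fr, noise_sd = noise_sd,
                     seed = s)$values
      else x
      vapply(names(scorers), function(nm) {
        sc <- scorers[[nm]](xs, s)
        rep <- metrics_report(sc, labels, k = k)
        c(fdr = rep$fdr, far = rep$far)
      }, numeric(2))
    })
    # average the 2 x n_scorers slabs over seeds
    acc <- Reduce(`+`, per_seed) / length(per_seed)
    rows[[length(rows) + 1]] <-
      data.frame(scorer = colnames(acc), fraction = fr,
                 fdr = acc["fdr", ], far = acc["far", ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Preprocessing ablation
#'
#' Evaluates every scorer on the raw indicator values and on the
#' direction-aware normalized values of the same batch, reporting paired
#' FDR/FAR. Indicators with large raw magnitudes (acidity, nonfat milk
#' solids) dominate Euclidean geometry on the raw view, which is what the
#' normalization removes.
#'
#' @param batch An [inspection_batch].
#' @param labels Qualification labels (default: `qualify(batch)`).
#' @inheritParams run_benchmark
#' @return A data frame with one row per scorer x view: `scorer`, `view`
#'   (`"raw"`/`"normalized"`), `fdr`, `far`.
#' @export
run_preprocessing_ablation <- function(batch, labels = NULL,
                                       scorers = .default_scorers(),
                                       seeds = 1:5, k = NULL) {
  stopifnot(inherits(batch, "inspection_batch"))
  if (is.null(labels)) labels <- qualify(batch)
  views <- list(raw = batch$values,
                normalized = normalize_batch(batch)$values)
  rows <- lapply(names(views), function(v) {
    b <- run_benchmark(views[[v]], labels, scorers = scorers, seeds = seeds,
                       k = k)
    data.frame(scorer = b$scorer, view = v, fdr = b$fdr, far = b$far)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
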