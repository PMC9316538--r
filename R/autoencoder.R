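#' Fit an auto-encoder anomaly scorer
#'
#' Fits a fully connected auto-encoder to a normalized inspection batch and
#' scores every sample by its squared reconstruction error
#' `k_i = || z_i - x_i ||^2`. The encoder maps `y = sigma(W x + b)` layer by
#' layer down to a low-dimensional code and the symmetric decoder maps back
#' `z = sigma(W~ y + b~)`; training minimizes the summed squared
#' reconstruction error plus a weight penalty,
#' `sum_i || z_i - x_i ||^2 + lambda * || W ||_F` over the encoder weights,
#' by Adam. Because the overwhelming majority of inspection samples are
#' qualified, the fitted network reconstructs the bulk well while
#' out-of-specification samples, which deviate from that distribution,
#' incur large reconstruction errors -- the anomaly score.
#'
#' With `noise_sd > 0` the model is a denoising auto-encoder (DAE): at every
#' epoch the training inputs are corrupted with zero-mean Gaussian noise,
#' `x^ = x + eps`, but the reconstruction error is measured against the
#' clean inputs, which yields representations robust to noisy or partially
#' missing readings. Scoring always uses the clean inputs; corruption is a
#' training-time device only.
#'
#' Training is unsupervised and, by default, transductive: the model is fit
#' on the whole batch being screened. For new samples, score them against a
#' previously fitted model with [predict.risk_ae()].
#'
#' @param x A `"normalized_batch"` from [normalize_batch()], or a plain
#'   numeric matrix of normalized values (samples in rows).
#' @param hidden Integer vector of encoder layer widths; the decoder mirrors
#'   them. Default `c(4, 2)`, i.e. a 6-4-2-4-6 network on six indicators.
#' @param activation Activation applied at every layer: `"sigmoid"`
#'   (default), `"tanh"`, `"relu"` or `"linear"`.
#' @param lambda Regularization strength in `[0, 1]` multiplying the
#'   Frobenius norm of the encoder weights (default 0.1).
#' @param epochs Number of Adam epochs (default 1000). `epochs = 0` returns
#'   the seeded initialization unchanged.
#' @param learning_rate Adam step size (default 5e-3).
#' @param batch_size Mini-batch size; default the full batch.
#' @param noise_sd Training-time corruption SD; 0 (default) fits a vanilla
#'   AE, positive values a DAE.
#' @param seed Integer seed controlling initialization (and corruption for
#'   a DAE); the same seed reproduces the fit exactly.
#' @return An object of class `"risk_ae"`: list with `params` (weights),
#'   `config`, `loss_history` (objective per epoch), `initial_loss`,
#'   `final_loss` (clean reconstruction objective before/after training),
#'   `scores` (training-sample anomaly scores), `column_stats` (if `x` was
#'   a normalized batch), `sample_id`, `call`.
#' @examples
#' sim <- simulate_milk_batch(n = 120, contamination = 0.05, seed = 3)
#' nb <- normalize_batch(sim$batch)
#' fit <- risk_autoencoder(nb, epochs = 200, seed = 1)
#' fit
#' @seealso [predict.risk_ae()], [ae_score()], [find_thresholds()]
#' @export
risk_autoencoder <- function(x, hidden = c(4, 2),
                             activation = c("sigmoid", "tanh", "relu",
                                            "linear"),
                             lambda = 0.1, epochs = 1000,
                             learning_rate = 5e-3, batch_size = NULL,
                             noise_sd = 0, seed = 1) {
  activation <- match.arg(activation)
  cl <- match.call()
  column_stats <- NULL; sample_id <- NULL
  if (inherits(x, "normalized_batch")) {
    column_stats <- x$column_stats
    sample_id <- x$sample_id
    x <- x$values
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) stop("x must be finite")
  n <- nrow(x); m <- ncol(x)
  hidden <- as.integer(hidden)
  if (any(hidden < 1)) stop("hidden layer widths must be positive")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(batch_size)) batch_size <- n
  batch_size <- min(as.integer(batch_size), n)
  if (batch_size < 1) stop("batch_size must be at least 1")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  params <- ae_init(m, hidden)

  adam <- .adam_state(params)
  loss_history <- numeric(0)
  initial_loss <- ae_loss(params, x, lambda, activation)
  full_batch <- batch_size >= n

  if (epochs > 0) {
    for (epoch in seq_len(epochs)) {
      xin <- if (noise_sd > 0)
        x + matrix(stats::rnorm(n * m, sd = noise_sd), n, m) else x
      idx_order <- if (full_batch) seq_len(n) else sample.int(n)
      epoch_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- idx_order[start:min(start + batch_size - 1, n)]
        g <- .ae_grad(params, xin[idx, , drop = FALSE],
                      x[idx, , drop = FALSE], lambda, activation)
        adam <- .adam_step(adam, params, g$grad, learning_rate)
        params <- adam$params
        epoch_loss <- epoch_loss + g$recon_loss
      }
      epoch_loss <- epoch_loss +
        lambda * .encoder_frobenius(params)
      if (!is.finite(epoch_loss))
        stop("non-finite loss at epoch ", epoch,
             "; lower the learning rate or check the inputs")
      loss_history[epoch] <- epoch_loss
    }
  }

  scores <- ae_score(params, x, activation)
  structure(list(params = params,
                 config = list(hidden = hidden, activation = activation,
                               lambda = lambda, epochs = epochs,
                               learning_rate = learning_rate,
                               batch_size = batch_size,
                               noise_sd = noise_sd, seed = seed,
                               input_dim = m, n_train = n),
                 loss_history = loss_history,
                 initial_loss = initial_loss,
                 final_loss = ae_loss(params, x, lambda, activation),
                 scores = scores,
                 column_stats = column_stats,
                 sample_id = sample_id,
                 call = cl),
            class = "risk_ae")
}

#' Auto-encoder parameter container
#'
#' `ae_init()` draws a fresh parameter set for a symmetric auto-encoder:
#' a list of weight matrices `W` and bias vectors `b`, one pair per layer,
#' with layer dimensions `m, hidden..., rev(hidden)[-1], m`. Weights use a
#' uniform Glorot draw scaled by fan-in/fan-out; biases start at zero. The
#' draw consumes the current RNG stream (seed it for reproducibility).
#'
#' @param m Input dimension.
#' @param hidden Integer vector of encoder widths.
#' @return A list with `W` (list of matrices), `b` (list of vectors) and
#'   `n_encoder` (number of encoder layers).
#' @export
ae_init <- function(m, hidden = c(4, 2)) {
  hidden <- as.integer(hidden)
  dims <- c(m, hidden, rev(hidden)[-1], m)
  W <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    s <- sqrt(6 / (dims[l] + dims[l + 1]))
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -s, s),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b, n_encoder = length(hidden))
}

.activations <- list(
  sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                 df = function(z, a) a * (1 - a)),
  tanh    = list(f = tanh, df = function(z, a) 1 - a^2),
  relu    = list(f = function(z) pmax(z, 0),
                 df = function(z, a) (z > 0) * 1),
  linear  = list(f = identity, df = function(z, a) 1))

#' Forward pass of an auto-encoder
#'
#' Propagates samples through encoder and decoder:
#' `y = sigma(W x + b)` at each layer. Returns the bottleneck code and the
#' reconstruction.
#'
#' @param params Parameters from [ae_init()] (or a fitted model's
#'   `$params`).
#' @param x A length-m vector or an n x m matrix.
#' @param activation Activation name (see [risk_autoencoder()]).
#' @return A list with `hidden` (bottleneck activations) and
#'   `reconstruction`, both matrices with one row per sample.
#' @export
ae_forward <- function(params, x, activation = "sigmoid") {
  act <- .activations[[match.arg(activation, names(.activations))]]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(params$W[[1]]))
    stop("input has ", ncol(x), " columns but the encoder expects ",
         nrow(params$W[[1]]))
  a <- x
  hidden <- NULL
  for (l in seq_along(params$W)) {
    a <- act$f(sweep(a %*% params$W[[l]], 2, params$b[[l]], "+"))
    if (l == params$n_encoder) hidden <- a
  }
  list(hidden = hidden, reconstruction = a)
}

# forward pass keeping every layer's pre-activation and activation,
# for backpropagation
.ae_forward_full <- function(params, x, act) {
  L <- length(params$W)
  zs <- vector("list", L); as_ <- vector("list", L + 1)
  as_[[1]] <- x
  for (l in seq_len(L)) {
    zs[[l]] <- sweep(as_[[l]] %*% params$W[[l]], 2, params$b[[l]], "+")
    as_[[l + 1]] <- act$f(zs[[l]])
  }
  list(z = zs, a = as_)
}

.encoder_frobenius <- function(params) {
  enc <- params$W[seq_len(params$n_encoder)]
  sqrt(sum(vapply(enc, function(w) sum(w^2), numeric(1))))
}

#' Auto-encoder training objectives
#'
#' `ae_loss()` is the vanilla objective: the squared reconstruction error
#' summed over samples plus `lambda` times the Frobenius norm of the
#' encoder weights, `sum_i || z_i - x_i ||^2 + lambda * || W ||_F`.
#' `dae_loss()` is the denoising objective: the reconstruction is computed
#' from Gaussian-corrupted inputs `x^ = x + eps` but the error is measured
#' against the clean inputs.
#'
#' @param params Auto-encoder parameters.
#' @param x Numeric matrix of (clean) samples in rows.
#' @param lambda Regularization strength.
#' @param activation Activation name.
#' @return A non-negative scalar.
#' @export
ae_loss <- function(params, x, lambda = 0, activation = "sigmoid") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  z <- ae_forward(params, x, activation)$reconstruction
  sum((z - x)^2) + lambda * .encoder_frobenius(params)
}

#' @rdname ae_loss
#' @param noise_sd Corruption SD; must be positive (use [ae_loss()] for the
#'   noise-free objective).
#' @param seed Integer seed for the corruption draw.
#' @export
dae_loss <- function(params, x, lambda = 0, noise_sd, seed = 1,
                     activation = "sigmoid") {
  if (noise_sd <= 0)
    stop("noise_sd must be positive for the denoising objective; ",
         "use ae_loss() for the noise-free case")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  xc <- corrupt_input(x, noise_sd, seed = seed)
  z <- ae_forward(params, xc, activation)$reconstruction
  sum((z - x)^2) + lambda * .encoder_frobenius(params)
}

#' Gaussian input corruption
#'
#' Draws the corrupted input `x^ = x + eps` with `eps ~ N(0, noise_sd^2)`
#' independently per coordinate. With `noise_sd = 0` the input is returned
#' unchanged.
#'
#' @param x Numeric vector or matrix.
#' @param noise_sd Non-negative corruption SD.
#' @param seed Optional integer seed; when supplied the draw is made on a
#'   private RNG stream, leaving the caller's stream untouched.
#' @return `x` plus noise, same shape.
#' @export
corrupt_input <- function(x, noise_sd, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (noise_sd == 0) return(x)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  x + stats::rnorm(length(x), sd = noise_sd)
}

#' Anomaly scores from reconstruction error
#'
#' Computes `k_i = || z_i - x_i ||^2`, the squared reconstruction error of
#' each sample. Scoring always uses the clean inputs, for vanilla and
#' denoising auto-encoders alike.
#'
#' @param params Auto-encoder parameters (or a `"risk_ae"` fit, in which
#'   case its stored activation is used).
#' @param x Numeric matrix of samples in rows (or a `"normalized_batch"`).
#' @param activation Activation name (ignored when `params` is a fit).
#' @return Numeric vector of non-negative scores, one per row.
#' @export
ae_score <- function(params, x, activation = "sigmoid") {
  if (inherits(params, "risk_ae")) {
    activation <- params$config$activation
    params <- params$params
  }
  if (inherits(x, "normalized_batch")) x <- x$values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  z <- ae_forward(params, x, activation)$reconstruction
  rowSums((z - x)^2)
}

# gradient of sum ||z - x_target||^2 (+ lambda * ||W_enc||_F) wrt all
# parameters; inputs x_in may be corrupted while x_target stays clean
.ae_grad <- function(params, x_in, x_target, lambda, activation) {
  act <- .activations[[activation]]
  L <- length(params$W)
  fwd <- .ae_forward_full(params, x_in, act)
  z <- fwd$a[[L + 1]]
  recon_loss <- sum((z - x_target)^2)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- 2 * (z - x_target) * act$df(fwd$z[[L]], fwd$a[[L + 1]])
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1)
      delta <- (delta %*% t(params$W[[l]])) *
        act$df(fwd$z[[l - 1]], fwd$a[[l]])
  }
  if (lambda > 0) {
    fro <- .encoder_frobenius(params)
    if (fro > 0)
      for (l in seq_len(params$n_encoder))
        gW[[l]] <- gW[[l]] + lambda * params$W[[l]] / fro
  }
  list(grad = list(W = gW, b = gb), recon_loss = recon_loss)
}

.adam_state <- function(params) {
  zeros <- function(p) lapply(p, function(x) x * 0)
  list(params = params,
       mW = zeros(params$W), vW = zeros(params$W),
       mb = zeros(params$b), vb = zeros(params$b),
       t = 0)
}

.adam_step <- function(state, params, grad, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grad$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grad$W[[l]]^2
    mhat <- state$mW[[l]] / (1 - beta1^t)
    vhat <- state$vW[[l]] / (1 - beta2^t)
    params$W[[l]] <- params$W[[l]] - lr * mhat / (sqrt(vhat) + eps)

    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grad$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grad$b[[l]]^2
    mhat <- state$mb[[l]] / (1 - beta1^t)
    vhat <- state$vb[[l]] / (1 - beta2^t)
    params$b[[l]] <- params$b[[l]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state$params <- params
  state
}

#' @export
print.risk_ae <- function(x, ...) {
  cfg <- x$config
  kind <- if (cfg$noise_sd > 0) "Denoising auto-encoder" else "Auto-encoder"
  dims <- c(cfg$input_dim, cfg$hidden, rev(cfg$hidden)[-1], cfg$input_dim)
  cat(kind, "anomaly scorer (", paste(dims, collapse = "-"), ", ",
      cfg$activation, ")\n", sep = "")
  cat("Trained on", cfg$n_train, "samples,", cfg$epochs, "epochs, lambda =",
      cfg$lambda, if (cfg$noise_sd > 0)
        paste0(", corruption sd = ", cfg$noise_sd), "\n")
  cat("Objective:", format(x$initial_loss, digits = 5), "->",
      format(x$final_loss, digits = 5), "\n")
  invisible(x)
}

#' @export
summary.risk_ae <- function(object, ...) {
  s <- object$scores
  out <- list(config = object$config,
              initial_loss = object$initial_loss,
              final_loss = object$final_loss,
              score_summary = summary(s),
              n = length(s))
  class(out) <- "summary.risk_ae"
  out
}

#' @export
print.summary.risk_ae <- function(x, ...) {
  cfg <- x$config
  dims <- c(cfg$input_dim, cfg$hidden, rev(cfg$hidden)[-1], cfg$input_dim)
  cat("Auto-encoder anomaly scorer\n")
  cat("  architecture:", paste(dims, collapse = "-"), "/", cfg$activation,
      "\n")
  cat("  epochs:", cfg$epochs, " lr:", cfg$learning_rate,
      " lambda:", cfg$lambda, " noise_sd:", cfg$noise_sd,
      " seed:", cfg$seed, "\n")
  cat("  training objective:", format(x$initial_loss, digits = 5), "->",
      format(x$final_loss, digits = 5), "\n")
  cat("  anomaly scores over", x$n, "training samples:\n")
  print(x$score_summary)
  invisible(x)
}

#' Predict anomaly scores for new samples
#'
#' @param object A `"risk_ae"` fit.
#' @param newdata A numeric matrix or `"normalized_batch"`; defaults to
#'   nothing, returning the training scores. New batches must be normalized
#'   with the reference batch's frozen column statistics (see
#'   [normalize_batch()]'s `stats` argument) for the scores to be
#'   comparable.
#' @param type `"score"` (default), `"reconstruction"` or `"hidden"`.
#' @param ... Unused.
#' @return A score vector or a matrix, by `type`.
#' @export
predict.risk_ae <- function(object, newdata = NULL,
                            type = c("score", "reconstruction", "hidden"),
                            ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "score") return(object$scores)
    stop("stored fits keep only scores; supply newdata for ", type)
  }
  if (inherits(newdata, "normalized_batch")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (type == "score")
    return(ae_score(object$params, newdata, object$config$activation))
  fwd <- ae_forward(object$params, newdata, object$config$activation)
  if (type == "reconstruction") fwd$reconstruction else fwd$hidden
}

#' @export
fitted.risk_ae <- function(object, ...) {
  stop("reconstructions are not stored; use predict(object, newdata, ",
       "type = 'reconstruction')")
}

#' Reconstruction residuals
#'
#' @param object A `"risk_ae"` fit.
#' @param newdata Samples to reconstruct (matrix or `"normalized_batch"`).
#' @param ... Unused.
#' @return Matrix of residuals `x - z` (input minus reconstruction).
#' @export
residuals.risk_ae <- function(object, newdata, ...) {
  if (inherits(newdata, "normalized_batch")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata - predict(object, newdata, type = "reconstruction")
}

#' @export
coef.risk_ae <- function(object, ...) object$params

#' Diagnostic plots for a fitted scorer
#'
#' `which = 1` draws the training objective per epoch; `which = 2` the
#' per-sample anomaly scores in batch order (log scale), the usual view for
#' spotting the separated high-risk tail.
#'
#' @param x A `"risk_ae"` fit.
#' @param which Plots to draw (subset of `1:2`).
#' @param ... Passed to the underlying plot calls.
#' @export
plot.risk_ae <- function(x, which = 1:2, ...) {
  if (1 %in% which && length(x$loss_history))
    graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                   xlab = "epoch", ylab = "training objective",
                   main = "Auto-encoder training", ...)
  if (2 %in% which)
    graphics::plot(seq_along(x$scores), x$scores, log = "y", pch = 20,
                   xlab = "sample index",
                   ylab = "reconstruction error (log scale)",
                   main = "Anomaly scores", ...)
  invisible(x)
}

#' Serialize a fitted scorer to JSON
#'
#' Stores the configuration, seed, weights and (when available) the
#' normalization column statistics in a portable JSON container, so new CSV
#' batches can be scored without the original training session.
#'
#' @param object A `"risk_ae"` fit.
#' @param path Output JSON path.
#' @return Invisibly, `path`. `read_risk_ae()` returns the restored
#'   `"risk_ae"` object (without training scores).
#' @export
write_risk_ae <- function(object, path) {
  stopifnot(inherits(object, "risk_ae"))
  payload <- list(
    container = "asrws-risk-ae",
    version = 1L,
    config = object$config,
    W = lapply(object$params$W, function(w)
      list(dim = dim(w), data = as.numeric(w))),
    b = object$params$b,
    n_encoder = object$params$n_encoder,
    column_stats = object$column_stats)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_risk_ae
#' @export
read_risk_ae <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(p$container) || p$container != "asrws-risk-ae")
    stop("not an asrws model container: ", path)
  W <- lapply(p$W, function(w) {
    d <- as.integer(unlist(w$dim))
    matrix(as.numeric(unlist(w$data)), d[1], d[2])
  })
  b <- lapply(p$b, function(v) as.numeric(unlist(v)))
  params <- list(W = W, b = b, n_encoder = as.integer(p$n_encoder))
  cfg <- lapply(p$config, unlist)
  cfg$hidden <- as.integer(cfg$hidden)
  column_stats <- if (!is.null(p$column_stats) && length(p$column_stats)) {
    rows <- lapply(p$column_stats, function(r)
      data.frame(name = r$name, min = r$min, max = r$max, mean = r$mean,
                 stringsAsFactors = FALSE))
    do.call(rbind, rows)
  } else NULL
  structure(list(params = params, config = cfg,
                 loss_history = numeric(0),
                 initial_loss = NA_real_, final_loss = NA_real_,
                 scores = NULL,
                 column_stats = column_stats,
                 sample_id = NULL, call = NULL),
            class = "risk_ae")
}
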