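test_that("forward pass closed forms hold", {
  # zero weights, sigmoid: every activation is 0.5
  p0 <- list(W = list(matrix(0, 3, 2), matrix(0, 2, 3)),
             b = list(numeric(2), numeric(3)), n_encoder = 1L)
  f <- ae_forward(p0, c(0.3, -1, 2), "sigmoid")
  expect_equal(as.numeric(f$hidden), rep(0.5, 2))
  expect_equal(as.numeric(f$reconstruction), rep(0.5, 3))

  # identity-configured linear net reproduces its input
  pid <- identity_params(4)
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(ae_forward(pid, x, "linear")$reconstruction, x)

  # 2-1-2 sigmoid net with hand-picked weights vs a step-by-step evaluation
  W1 <- matrix(c(0.7, -0.3), 2, 1); b1 <- 0.1
  W2 <- matrix(c(0.5, -1.2), 1, 2); b2 <- c(-0.2, 0.4)
  p <- list(W = list(W1, W2), b = list(b1, b2), n_encoder = 1L)
  x <- matrix(c(0.2, 0.9, -0.4, 0.1), 2, 2)
  want <- hand_forward_212(x, W1, b1, W2, b2)
  got <- ae_forward(p, x, "sigmoid")
  expect_equal(got$hidden, want$y)
  expect_equal(got$reconstruction, want$z)

  expect_error(ae_forward(p, c(1, 2, 3), "sigmoid"), "expects")
})

test_that("the training objective decomposes into error plus penalty", {
  pid <- identity_params(3)
  x <- matrix(runif(12), 4, 3)
  # perfect reconstruction, no penalty
  expect_equal(ae_loss(pid, x, lambda = 0, activation = "linear"), 0)
  # penalty-only: loss equals the Frobenius norm of the encoder weights
  expect_equal(ae_loss(pid, x, lambda = 1, activation = "linear"),
               sqrt(sum(diag(3)^2)))
  # fixed imperfect reconstruction: zero-weight sigmoid always outputs 0.5
  p0 <- list(W = list(matrix(0, 3, 2), matrix(0, 2, 3)),
             b = list(numeric(2), numeric(3)), n_encoder = 1L)
  expect_equal(ae_loss(p0, x, lambda = 0), sum((0.5 - x)^2))
})

test_that("gaussian corruption has the declared moments and determinism", {
  x <- 1.5
  expect_identical(corrupt_input(x, 0), x)
  draws <- corrupt_input(rep(x, 1e5), 0.1, seed = 5) - x
  expect_lt(abs(sd(draws) - 0.1) / 0.1, 0.02)
  expect_lt(abs(mean(draws)), 0.005)
  expect_identical(corrupt_input(1:10 / 10, 0.3, seed = 2),
                   corrupt_input(1:10 / 10, 0.3, seed = 2))
})

test_that("the denoising objective measures error against the clean input", {
  set.seed(3)
  p <- ae_init(3, c(2))
  x <- matrix(runif(15), 5, 3)
  expect_error(dae_loss(p, x, lambda = 0, noise_sd = 0), "ae_loss")
  # vanishing-noise limit recovers the clean objective
  expect_equal(dae_loss(p, x, lambda = 0.1, noise_sd = 1e-8, seed = 1),
               ae_loss(p, x, lambda = 0.1), tolerance = 1e-4)
  # composed oracle: corrupt, forward, compare to clean input by hand
  xc <- corrupt_input(x, 0.2, seed = 7)
  z <- ae_forward(p, xc, "sigmoid")$reconstruction
  expect_equal(dae_loss(p, x, lambda = 0.3, noise_sd = 0.2, seed = 7),
               sum((z - x)^2) + 0.3 * sqrt(sum(p$W[[1]]^2)))
  # a perfect autoencoder still scores > 0 against the clean input
  pid <- identity_params(3)
  expect_gt(dae_loss(pid, x, lambda = 0, noise_sd = 0.5, seed = 1,
                     activation = "linear"), 0)
})

test_that("epochs = 0 returns the seeded initialization unchanged", {
  x <- matrix(runif(60), 10, 6)
  fit <- risk_autoencoder(x, epochs = 0, seed = 42)
  set.seed(42)
  expect_equal(fit$params, ae_init(6, c(4, 2)))
  expect_length(fit$loss_history, 0)
})

test_that("training reduces the objective and is seed-deterministic", {
  sim <- simulate_milk_batch(n = 100, contamination = 0.05, seed = 2)
  nb <- normalize_batch(sim$batch)
  fit <- risk_autoencoder(nb, epochs = 300, seed = 1)
  expect_lt(fit$final_loss, fit$initial_loss)
  # loss curve non-increasing over epoch-averaged windows
  w <- matrix(fit$loss_history, nrow = 50)
  expect_true(all(diff(colMeans(w)) < 0))
  fit2 <- risk_autoencoder(nb, epochs = 300, seed = 1)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$scores, fit2$scores)
  expect_false(identical(
    fit$params, risk_autoencoder(nb, epochs = 300, seed = 2)$params))
})

test_that("scores are squared reconstruction errors on clean inputs", {
  pid <- identity_params(3)
  x <- matrix(runif(9), 3, 3)
  expect_equal(ae_score(pid, x, "linear"), rep(0, 3))

  set.seed(8)
  p <- ae_init(3, 2)
  z <- ae_forward(p, x, "sigmoid")$reconstruction
  want <- sapply(1:3, function(i) sum((z[i, ] - x[i, ])^2))
  expect_equal(ae_score(p, x, "sigmoid"), want)
})

test_that("trained scores separate planted failures from the bulk", {
  sim <- simulate_milk_batch(n = 300, contamination = 0.05, seed = 4)
  nb <- normalize_batch(sim$batch)
  fit <- risk_autoencoder(nb, seed = 1)
  unq <- sim$labels$labels == "unqualified"
  expect_gt(mean(fit$scores[unq]), mean(fit$scores[!unq]))
})

test_that("full-batch AE scores are equivariant to row permutation", {
  sim <- simulate_milk_batch(n = 80, contamination = 0.05, seed = 5)
  x <- normalize_batch(sim$batch)$values
  fit <- risk_autoencoder(x, epochs = 200, seed = 3)
  perm <- sample(nrow(x))
  fitp <- risk_autoencoder(x[perm, ], epochs = 200, seed = 3)
  expect_equal(fitp$scores, fit$scores[perm])
})

test_that("scorer baselines and AE are permutation-equivariant", {
  set.seed(6)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10, 5, 5, 0, 0), 4, 3)
  x <- centers[rep(1:4, each = 10), ] + matrix(rnorm(120, sd = 0.2), 40, 3)
  perm <- sample(40)
  expect_equal(knn_score(x[perm, ], k = 3), knn_score(x, k = 3)[perm])
  expect_equal(kmeans_score(x[perm, ], 4, seed = 1),
               kmeans_score(x, 4, seed = 1)[perm], tolerance = 1e-8)
})

test_that("a linear bottleneck autoencoder attains the PCA reconstruction error", {
  set.seed(42)
  n <- 80
  x <- cbind(rnorm(n, sd = 2), rnorm(n, sd = 0.3))
  x <- x %*% matrix(c(cos(0.6), sin(0.6), -sin(0.6), cos(0.6)), 2)
  x <- scale(x, scale = FALSE)
  pc <- prcomp(x, center = FALSE)
  xhat <- pc$x[, 1, drop = FALSE] %*% t(pc$rotation[, 1, drop = FALSE])
  pca_err <- sum((x - xhat)^2)
  fit <- risk_autoencoder(x, hidden = 1, activation = "linear", lambda = 0,
                          epochs = 2000, seed = 1)
  expect_lt(fit$final_loss, pca_err * 1.05)
  expect_gt(fit$final_loss, pca_err * (1 - 1e-6))  # PCA is the optimum
})

test_that("fits serialize to JSON and score identically after reload", {
  sim <- simulate_milk_batch(n = 60, contamination = 0.05, seed = 9)
  nb <- normalize_batch(sim$batch)
  fit <- risk_autoencoder(nb, epochs = 100, seed = 1)
  path <- tempfile(fileext = ".json")
  write_risk_ae(fit, path)
  back <- read_risk_ae(path)
  expect_equal(predict(back, nb$values), fit$scores)
  expect_equal(back$column_stats$min, nb$column_stats$min)
  expect_equal(back$config$hidden, fit$config$hidden)
  unlink(path)
})

test_that("degenerate configurations are rejected", {
  x <- matrix(runif(30), 10, 3)
  expect_error(risk_autoencoder(x, lambda = 2), "lambda")
  expect_error(risk_autoencoder(x, noise_sd = -1), "noise_sd")
  x[1, 1] <- NA
  expect_error(risk_autoencoder(x), "finite")
})
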