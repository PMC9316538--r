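# Fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (per-element loops, all-pairs enumeration) and share no
# code with the implementation they check.

toy_specs <- function() {
  indicator_specs(data.frame(
    name = c("a_min", "b_max", "c_int"),
    unit = c("u", "u", "u"),
    bound_kind = c("min_limit", "max_limit", "interval"),
    lo = c(2, NA, 10),
    hi = c(NA, 5, 20),
    standard_ref = ""))
}

toy_batch <- function(values, specs = toy_specs()) {
  colnames(values) <- specs$name
  inspection_batch(values, specs)
}

# random batch on the toy spec scale, mixing in-bound and out-of-bound values
random_toy_batch <- function(n, seed) {
  set.seed(seed)
  v <- cbind(runif(n, 1, 4), runif(n, 3, 7), runif(n, 5, 25))
  toy_batch(v)
}

# rule-by-rule qualification, looping over every cell
oracle_qualify <- function(batch) {
  specs <- batch$specs
  x <- batch$values
  labels <- character(nrow(x))
  violated <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    bad <- character(0)
    for (j in seq_len(ncol(x))) {
      v <- x[i, j]
      ok <- if (specs$bound_kind[j] == "min_limit") v >= specs$lo[j]
            else if (specs$bound_kind[j] == "max_limit") v <= specs$hi[j]
            else v >= specs$lo[j] && v <= specs$hi[j]
      if (!ok) bad <- c(bad, specs$name[j])
    }
    violated[[i]] <- bad
    labels[i] <- if (length(bad)) "unqualified" else "qualified"
  }
  list(labels = labels, violated = violated)
}

# element-wise recomputation of the three normalization branches
oracle_normalize <- function(batch, interval_absolute = FALSE) {
  x <- batch$values
  specs <- batch$specs
  out <- x
  for (j in seq_len(ncol(x))) {
    mn <- min(x[, j]); mx <- max(x[, j]); mu <- mean(x[, j])
    for (i in seq_len(nrow(x))) {
      out[i, j] <- switch(specs$bound_kind[j],
        max_limit = (x[i, j] - mn) / (mx - mn),
        min_limit = 1 - (x[i, j] - mn) / (mx - mn),
        interval  = {
          d <- (x[i, j] - mu) / (mx - mn)
          if (interval_absolute) abs(d) else d
        })
    }
  }
  out
}

# all-pairs AUC enumeration with half-credit for ties
oracle_auc <- function(scores, unqualified) {
  pos <- scores[unqualified]
  neg <- scores[!unqualified]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive top-k tabulation using an independently computed ranking
oracle_confusion <- function(scores, unqualified, k) {
  ord <- order(scores, decreasing = TRUE)
  # replicate the stable index tie-break without order()'s multi-key form
  ord <- ord[order(-scores[ord], ord)]
  pred <- rep(FALSE, length(scores))
  pred[ord[1:k]] <- TRUE
  list(TP = sum(pred & unqualified), FP = sum(pred & !unqualified),
       FN = sum(!pred & unqualified), TN = sum(!pred & !unqualified))
}

# comparator stripping re-done with substring logic only
oracle_clean_cell <- function(cell) {
  cell <- trimws(cell)
  if (substr(cell, 1, 1) %in% c("<", ">"))
    cell <- substr(cell, 2, nchar(cell))
  as.numeric(cell)
}

# a 2-1-2 sigmoid net with hand-picked weights, evaluated step by step
hand_forward_212 <- function(x, W1, b1, W2, b2) {
  sig <- function(z) 1 / (1 + exp(-z))
  y <- sig(x %*% W1 + matrix(b1, nrow(x), length(b1), byrow = TRUE))
  z <- sig(y %*% W2 + matrix(b2, nrow(x), length(b2), byrow = TRUE))
  list(y = y, z = z)
}

# identity-configured linear autoencoder on m inputs (hidden width m)
identity_params <- function(m) {
  list(W = list(diag(m), diag(m)), b = list(numeric(m), numeric(m)),
       n_encoder = 1L)
}
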