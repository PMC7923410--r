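# Minimal single-hidden-layer feed-forward network for binary classification:
# leaky-ReLU hidden units, dropout after the hidden layer, sigmoid output,
# minibatch SGD on binary cross-entropy. Small enough (<=8 hidden units, a
# few features, tens of subjects) that plain R matrix ops suffice.

mlp_fit <- function(x, y, hidden = 4L, leaky_alpha = 0.01, dropout = 0,
                    batch_size = 8L, epochs = 100L, lr = 0.05, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(n == length(y), all(y %in% c(0, 1)))
  with_seed(seed, {
    W1 <- matrix(rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
    b1 <- rep(0, hidden)
    W2 <- matrix(rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
    b2 <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        m <- length(idx)
        z1 <- sweep(xb %*% W1, 2L, b1, `+`)
        a1 <- ifelse(z1 > 0, z1, leaky_alpha * z1)
        if (dropout > 0) {
          dm <- matrix(rbinom(m * hidden, 1L, 1 - dropout), m, hidden) / (1 - dropout)
          a1d <- a1 * dm
        } else {
          dm <- NULL
          a1d <- a1
        }
        z2 <- a1d %*% W2 + b2
        prob <- 1 / (1 + exp(-z2))
        # gradients of mean cross-entropy
        dz2 <- (prob - yb) / m
        dW2 <- t(a1d) %*% dz2
        db2 <- sum(dz2)
        da1 <- dz2 %*% t(W2)
        if (!is.null(dm)) da1 <- da1 * dm
        dz1 <- da1 * ifelse(z1 > 0, 1, leaky_alpha)
        dW1 <- t(xb) %*% dz1
        db1 <- colSums(dz1)
        W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
        W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2
      }
    }
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   leaky_alpha = leaky_alpha), class = "wearhrv_mlp")
  })
}

mlp_predict_prob <- function(model, x) {
  x <- as.matrix(x)
  z1 <- sweep(x %*% model$W1, 2L, model$b1, `+`)
  a1 <- ifelse(z1 > 0, z1, model$leaky_alpha * z1)
  drop(1 / (1 + exp(-(a1 %*% model$W2 + model$b2))))
}

# Random search over the hyperparameter box (hidden units 1-8, leaky slope
# 0-1, dropout 0-0.99, batch size 1-32) with a stratified 80/20
# train/validation split of the training data; picks the configuration with
# the best validation cross-entropy.
mlp_random_search <- function(x, y, n_configs = 400L, epochs = 100L, seed = 1L) {
  n <- nrow(x)
  idx_val <- with_seed(seed + 1L, stratified_take(y, fraction = 0.2))
  tr <- setdiff(seq_len(n), idx_val)
  configs <- with_seed(seed + 2L, data.frame(
    hidden = sample(1:8, n_configs, replace = TRUE),
    leaky_alpha = runif(n_configs, 0, 1),
    dropout = runif(n_configs, 0, 0.99),
    batch_size = sample(1:32, n_configs, replace = TRUE)
  ))
  best <- NULL; best_loss <- Inf
  eps <- 1e-12
  for (k in seq_len(n_configs)) {
    cfg <- configs[k, ]
    m <- mlp_fit(x[tr, , drop = FALSE], y[tr], hidden = cfg$hidden,
                 leaky_alpha = cfg$leaky_alpha, dropout = cfg$dropout,
                 batch_size = cfg$batch_size, epochs = epochs,
                 seed = seed + 100L + k)
    pv <- mlp_predict_prob(m, x[idx_val, , drop = FALSE])
    loss <- -mean(y[idx_val] * log(pv + eps) + (1 - y[idx_val]) * log(1 - pv + eps))
    if (loss < best_loss) { best_loss <- loss; best <- list(model = m, config = cfg) }
  }
  # refit the winning configuration on the full training data
  cfg <- best$config
  final <- mlp_fit(x, y, hidden = cfg$hidden, leaky_alpha = cfg$leaky_alpha,
                   dropout = cfg$dropout, batch_size = cfg$batch_size,
                   epochs = epochs, seed = seed + 3L)
  list(model = final, config = cfg, val_loss = best_loss)
}
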