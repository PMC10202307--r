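# Minimal single-hidden-layer regression network: ReLU activation, joint
# multi-output squared-error loss, ADAM minibatch optimization, early stopping
# on a 10% validation split with patience. Written in plain matrix algebra;
# all randomness (initialization, split, shuffling) flows from R's RNG so a
# seeded run is reproducible.

fit_mlp <- function(X, Z, hidden, max_epochs = 500L, patience = 10L,
                    val_frac = 0.1, batch_size = 64L, lr = 1e-3,
                    beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  n <- nrow(X); d_in <- ncol(X); d_out <- ncol(Z)
  stopifnot(n >= 2L, hidden >= 1L)

  n_val <- max(1L, floor(val_frac * n))
  idx <- sample.int(n)
  val <- idx[seq_len(n_val)]
  trn <- idx[-seq_len(n_val)]
  if (length(trn) < 1L) { trn <- idx; val <- idx }
  Xt <- X[trn, , drop = FALSE]; Zt <- Z[trn, , drop = FALSE]
  Xv <- X[val, , drop = FALSE]; Zv <- Z[val, , drop = FALSE]
  nt <- nrow(Xt)
  batch_size <- min(batch_size, nt)

  # He initialization for ReLU units; small positive biases avoid dead units
  par <- list(
    W1 = matrix(stats::rnorm(d_in * hidden, 0, sqrt(2 / d_in)), d_in, hidden),
    b1 = rep(0.1, hidden),
    W2 = matrix(stats::rnorm(hidden * d_out, 0, sqrt(2 / hidden)), hidden, d_out),
    b2 = numeric(d_out)
  )
  m <- lapply(par, function(p) p * 0)
  v <- lapply(par, function(p) p * 0)
  step <- 0L

  val_loss <- function(p) {
    H <- pmax(sweep(Xv %*% p$W1, 2L, p$b1, `+`), 0)
    P <- sweep(H %*% p$W2, 2L, p$b2, `+`)
    mean((P - Zv)^2)
  }

  best <- par
  best_loss <- val_loss(par)
  wait <- 0L

  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(nt)
    for (start in seq(1L, nt, by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1L, nt)]
      Xb <- Xt[rows, , drop = FALSE]; Zb <- Zt[rows, , drop = FALSE]
      nb <- nrow(Xb)

      A1 <- sweep(Xb %*% par$W1, 2L, par$b1, `+`)
      H <- pmax(A1, 0)
      P <- sweep(H %*% par$W2, 2L, par$b2, `+`)

      dP <- 2 * (P - Zb) / (nb * ncol(Zb))
      gW2 <- crossprod(H, dP)
      gb2 <- colSums(dP)
      dH <- dP %*% t(par$W2)
      dA1 <- dH * (A1 > 0)
      gW1 <- crossprod(Xb, dA1)
      gb1 <- colSums(dA1)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)

      step <- step + 1L
      for (nm in names(par)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^step)
        vhat <- v[[nm]] / (1 - beta2^step)
        par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }

    loss <- val_loss(par)
    if (loss < best_loss - 1e-12) {
      best_loss <- loss
      best <- par
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }

  c(best, list(hidden = hidden, val_loss = best_loss, epochs = epoch))
}

mlp_forward <- function(model, X) {
  H <- pmax(sweep(as.matrix(X) %*% model$W1, 2L, model$b1, `+`), 0)
  sweep(H %*% model$W2, 2L, model$b2, `+`)
}
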