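# Minimal multi-layer perceptron in base R (BLAS matrix ops): ReLU hidden
# layers, linear output, inverted dropout, Adam with L2 weight decay, and an
# exact reverse-mode Jacobian used by the gene-sensitivity scores.

mlp_init <- function(n_in, hidden, n_out = 2L, seed = 1L) {
  dims <- c(n_in, hidden, n_out)
  L <- length(dims) - 1L
  with_seed(seed, {
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- dims[l]
      sdv <- if (l < L) sqrt(2 / fan_in) else sqrt(1 / fan_in)   # He / Glorot-ish
      W[[l]] <- matrix(stats::rnorm(fan_in * dims[l + 1], sd = sdv), fan_in, dims[l + 1])
      b[[l]] <- rep(0, dims[l + 1])
    }
    list(W = W, b = b, dims = dims)
  })
}

# Forward pass. Returns output plus cached activations/masks for backprop.
mlp_forward <- function(net, X, dropout = 0, train = FALSE) {
  L <- length(net$W)
  A <- list(X)           # A[[l]]: input to layer l
  D <- vector("list", L) # ReLU masks (hidden layers)
  M <- vector("list", L) # dropout masks
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < L) {
      D[[l]] <- z > 0
      a <- z * D[[l]]
      if (train && dropout > 0) {
        M[[l]] <- matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a)) / (1 - dropout)
        a <- a * M[[l]]
      }
    } else {
      a <- z
    }
    if (l < L) A[[l + 1]] <- a
  }
  list(out = a, A = A, D = D, M = M)
}

# Weighted MSE loss: sum_j w_j ||yhat_j - y_j||^2 / sum_j w_j.
mlp_loss <- function(net, X, Y, w) {
  out <- mlp_forward(net, X)$out
  sum(w * rowSums((out - Y)^2)) / sum(w)
}

# One backward pass; returns gradients of the weighted MSE wrt W, b.
mlp_backward <- function(net, fwd, Y, w) {
  L <- length(net$W)
  n_w <- sum(w)
  delta <- 2 * (fwd$out - Y) * (w / n_w)   # d loss / d output
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(net$W[[l]])
      if (!is.null(fwd$M[[l - 1]])) delta <- delta * fwd$M[[l - 1]]
      delta <- delta * fwd$D[[l - 1]]
    }
  }
  list(W = gW, b = gb)
}

# input_noise: train-time jitter, sd = input_noise * per-feature sd. Noise on
# the inputs is a Tikhonov penalty on the input gradients, damping pathways
# that need fine input precision.
mlp_train <- function(X, Y, w = rep(1, nrow(X)), hidden = c(256L, 64L),
                      dropout = 0.2, lr = 1e-3, weight_decay = 1e-4,
                      max_epochs = 500L, patience = 20L, val_frac = 0.1,
                      batch_size = 128L, input_noise = 0, seed = 1L) {
  stopifnot(nrow(X) == nrow(Y), nrow(X) == length(w), all(w >= 0), all(is.finite(X)))
  n <- nrow(X)
  net <- mlp_init(ncol(X), hidden, ncol(Y), seed = seed)
  n_val <- max(1L, floor(val_frac * n))
  ord <- with_seed(seed + 1L, sample.int(n))
  val_idx <- ord[seq_len(n_val)]
  tr_idx <- ord[-seq_len(n_val)]
  if (length(tr_idx) == 0) { tr_idx <- val_idx }
  Xt <- X[tr_idx, , drop = FALSE]; Yt <- Y[tr_idx, , drop = FALSE]; wt <- w[tr_idx]
  Xv <- X[val_idx, , drop = FALSE]; Yv <- Y[val_idx, , drop = FALSE]; wv <- w[val_idx]
  if (all(wv == 0)) wv <- rep(1, length(wv))
  if (all(wt == 0)) stop("all training weights are zero")

  # Adam state
  L <- length(net$W)
  mW <- lapply(net$W, function(x) x * 0); vW <- mW
  mb <- lapply(net$b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

  train_log <- mlp_loss(net, Xt, Yt, wt)
  best_val <- mlp_loss(net, Xv, Yv, wv)
  best_net <- net
  stall <- 0L
  nt <- nrow(Xt)
  bs <- min(batch_size, nt)
  noise_sd <- if (input_noise > 0)
    input_noise * apply(Xt, 2, stats::sd) else NULL

  with_seed(seed + 2L, {
    for (epoch in seq_len(max_epochs)) {
      perm <- sample.int(nt)
      for (start in seq(1, nt, by = bs)) {
        idx <- perm[start:min(start + bs - 1, nt)]
        xb <- Xt[idx, , drop = FALSE]
        yb <- Yt[idx, , drop = FALSE]
        wb <- wt[idx]
        if (all(wb == 0)) next
        if (!is.null(noise_sd))
          xb <- xb + matrix(stats::rnorm(length(xb)), nrow(xb), ncol(xb)) *
            rep(noise_sd, each = nrow(xb))
        fwd <- mlp_forward(net, xb, dropout = dropout, train = TRUE)
        gr <- mlp_backward(net, fwd, yb, wb)
        t_step <- t_step + 1
        for (l in seq_len(L)) {
          gWl <- gr$W[[l]] + weight_decay * net$W[[l]]
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gWl
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gWl^2
          net$W[[l]] <- net$W[[l]] - lr * (mW[[l]] / (1 - beta1^t_step)) /
            (sqrt(vW[[l]] / (1 - beta2^t_step)) + eps)
          gbl <- gr$b[[l]]
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gbl
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gbl^2
          net$b[[l]] <- net$b[[l]] - lr * (mb[[l]] / (1 - beta1^t_step)) /
            (sqrt(vb[[l]] / (1 - beta2^t_step)) + eps)
        }
      }
      tl <- mlp_loss(net, Xt, Yt, wt)
      if (!is.finite(tl)) stop("non-finite training loss at epoch ", epoch)
      train_log <- c(train_log, tl)
      vl <- mlp_loss(net, Xv, Yv, wv)
      if (vl < best_val - 1e-12) {
        best_val <- vl
        best_net <- net
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  })
  net <- best_net
  final <- mlp_loss(net, Xt, Yt, wt)
  train_log <- c(train_log, final)
  list(net = net, train_log = train_log, val_loss = best_val)
}

# Exact Jacobian of the network output wrt its input.
# Returns a list with one m x n_in matrix per output dimension.
mlp_jacobian <- function(net, X) {
  L <- length(net$W)
  fwd <- mlp_forward(net, X)
  n_out <- ncol(net$W[[L]])
  m <- nrow(X)
  out <- vector("list", n_out)
  for (p in seq_len(n_out)) {
    g <- matrix(net$W[[L]][, p], m, nrow(net$W[[L]]), byrow = TRUE)
    for (l in rev(seq_len(L - 1))) {
      g <- g * fwd$D[[l]]
      g <- g %*% t(net$W[[l]])
    }
    out[[p]] <- g
  }
  out
}
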