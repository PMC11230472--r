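# Minimal feed-forward network engine: ReLU hidden layers, softmax output,
# cross-entropy loss, Adam updates, optional early stopping on a stratified
# validation split. Vectorized over minibatches with BLAS-backed matrix
# products; sizes here (thousands of cells, hundreds of features) do not
# warrant compiled code.

mlp_init <- function(sizes, rng_sd = NULL) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    # He initialization suits ReLU layers
    list(W = matrix(stats::rnorm(fan_in * sizes[l + 1L], 0,
                                 sqrt(2 / fan_in)),
                    fan_in, sizes[l + 1L]),
         b = rep(0, sizes[l + 1L]))
  })
}

mlp_forward <- function(params, x) {
  acts <- vector("list", length(params))
  a <- x
  for (l in seq_along(params)) {
    z <- a %*% params[[l]]$W
    z <- sweep(z, 2, params[[l]]$b, "+")
    if (l < length(params)) {
      a <- pmax(z, 0)
    } else {
      # row-wise softmax, shifted for stability
      z <- z - apply(z, 1, max)
      ez <- exp(z)
      a <- ez / rowSums(ez)
    }
    acts[[l]] <- a
  }
  acts
}

mlp_loss <- function(probs, y_onehot) {
  -mean(log(pmax(rowSums(probs * y_onehot), 1e-12)))
}

# one Adam step on a minibatch; returns updated params and moments
mlp_step <- function(params, moments, x, y_onehot, lr, t, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  n <- nrow(x)
  acts <- mlp_forward(params, x)
  L <- length(params)
  delta <- (acts[[L]] - y_onehot) / n
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1L) x else acts[[l - 1L]]
    gW <- crossprod(a_prev, delta)
    gb <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params[[l]]$W)) * (acts[[l - 1L]] > 0)
    }
    m <- moments[[l]]
    m$mW <- beta1 * m$mW + (1 - beta1) * gW
    m$vW <- beta2 * m$vW + (1 - beta2) * gW^2
    m$mb <- beta1 * m$mb + (1 - beta1) * gb
    m$vb <- beta2 * m$vb + (1 - beta2) * gb^2
    corr1 <- 1 - beta1^t
    corr2 <- 1 - beta2^t
    params[[l]]$W <- params[[l]]$W -
      lr * (m$mW / corr1) / (sqrt(m$vW / corr2) + eps)
    params[[l]]$b <- params[[l]]$b -
      lr * (m$mb / corr1) / (sqrt(m$vb / corr2) + eps)
    moments[[l]] <- m
  }
  list(params = params, moments = moments)
}

# x: n x d numeric; y: integer class index in 1..K. Deterministic given the
# caller's RNG state (all randomness -- init, shuffling, validation split --
# uses the current stream).
mlp_train <- function(x, y, n_classes, hidden_sizes, learning_rate = 1e-3,
                      max_epochs = 200L, batch_size = 64L,
                      early_stopping = TRUE, val_frac = 0.1,
                      patience = 10L) {
  n <- nrow(x)
  y_onehot <- matrix(0, n, n_classes)
  y_onehot[cbind(seq_len(n), y)] <- 1

  val_idx <- integer(0)
  if (early_stopping) {
    # stratified split so every class is represented in training
    for (k in seq_len(n_classes)) {
      members <- which(y == k)
      n_val <- floor(length(members) * val_frac)
      if (n_val >= 1 && length(members) - n_val >= 1) {
        val_idx <- c(val_idx, sample(members, n_val))
      }
    }
  }
  if (length(val_idx)) {
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    tr_idx <- seq_len(n)
    early_stopping <- FALSE
  }
  xt <- x[tr_idx, , drop = FALSE]
  yt <- y_onehot[tr_idx, , drop = FALSE]
  xv <- x[val_idx, , drop = FALSE]
  yv <- y_onehot[val_idx, , drop = FALSE]

  sizes <- c(ncol(x), hidden_sizes, n_classes)
  params <- mlp_init(sizes)
  moments <- lapply(params, function(p) {
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })

  best <- list(loss = Inf, params = params, epoch = 0L)
  bad_epochs <- 0L
  t_step <- 0L
  nt <- nrow(xt)
  for (epoch in seq_len(max_epochs)) {
    perm <- sample.int(nt)
    starts <- seq(1L, nt, by = batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1L, nt)]
      t_step <- t_step + 1L
      upd <- mlp_step(params, moments, xt[idx, , drop = FALSE],
                      yt[idx, , drop = FALSE], learning_rate, t_step)
      params <- upd$params
      moments <- upd$moments
    }
    if (early_stopping) {
      val_loss <- mlp_loss(mlp_forward(params, xv)[[length(params)]], yv)
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= patience) break
      }
    }
  }
  if (early_stopping) params <- best$params
  list(params = params,
       n_epochs = epoch,
       val_loss = if (early_stopping) best$loss else NA_real_)
}

mlp_predict_proba <- function(fit, x) {
  mlp_forward(fit$params, x)[[length(fit$params)]]
}
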