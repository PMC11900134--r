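# Minimal feed-forward network for the multiclass activity leg: dense layers
# with relu/tanh/sigmoid activations, a softmax head, categorical
# cross-entropy loss and Adam updates, trained full-batch.  Deliberately
# small: dense matrix algebra through BLAS, deterministic given the seed.

mlp_init <- function(n_in, hidden, n_out, activation, seed) {
  set.seed(seed)
  sizes <- c(n_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1), function(i) {
    fan_in <- sizes[i]; fan_out <- sizes[i + 1]
    sc <- if (activation == "relu") sqrt(2 / fan_in)
          else sqrt(2 / (fan_in + fan_out))          # Glorot for tanh/sigmoid
    list(W = matrix(rnorm(fan_in * fan_out, sd = sc), fan_in, fan_out),
         b = rep(0, fan_out))
  })
}

mlp_act <- function(Z, activation) {
  switch(activation,
         relu = pmax(Z, 0),
         tanh = tanh(Z),
         sigmoid = 1 / (1 + exp(-Z)))
}
mlp_act_grad <- function(A, activation) {
  switch(activation,
         relu = (A > 0) * 1,
         tanh = 1 - A^2,
         sigmoid = A * (1 - A))
}

mlp_forward <- function(layers, X, activation) {
  L <- length(layers)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (i in seq_len(L - 1)) {
    Z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    acts[[i + 1]] <- mlp_act(Z, activation)
  }
  Z <- sweep(acts[[L]] %*% layers[[L]]$W, 2, layers[[L]]$b, "+")
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z)
  P <- P / pmax(rowSums(P), .Machine$double.xmin)
  acts[[L + 1]] <- P
  acts
}

# Full-batch Adam on categorical cross-entropy.  Y is a one-hot matrix.
mlp_train <- function(X, Y, hidden, activation = "relu", lr = 1e-3,
                      epochs = 150, patience = 15, seed = 1L) {
  n <- nrow(X)
  layers <- mlp_init(ncol(X), hidden, ncol(Y), activation, seed)
  L <- length(layers)
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_loss <- Inf; best_layers <- layers; stall <- 0
  for (t in seq_len(epochs)) {
    acts <- mlp_forward(layers, X, activation)
    P <- acts[[L + 1]]
    loss <- -mean(rowSums(Y * log(pmax(P, 1e-12))))
    if (!is.finite(loss)) break   # diverged; keep the best weights so far
    if (loss < best_loss - 1e-6) {
      best_loss <- loss; best_layers <- layers; stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= patience) break
    }
    delta <- (P - Y) / n
    for (i in rev(seq_len(L))) {
      gW <- crossprod(acts[[i]], delta)
      gb <- colSums(delta)
      if (i > 1) {
        delta <- (delta %*% t(layers[[i]]$W)) * mlp_act_grad(acts[[i]], activation)
      }
      m[[i]]$W <- b1 * m[[i]]$W + (1 - b1) * gW
      m[[i]]$b <- b1 * m[[i]]$b + (1 - b1) * gb
      v[[i]]$W <- b2 * v[[i]]$W + (1 - b2) * gW^2
      v[[i]]$b <- b2 * v[[i]]$b + (1 - b2) * gb^2
      mhW <- m[[i]]$W / (1 - b1^t); mhb <- m[[i]]$b / (1 - b1^t)
      vhW <- v[[i]]$W / (1 - b2^t); vhb <- v[[i]]$b / (1 - b2^t)
      layers[[i]]$W <- layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
      layers[[i]]$b <- layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  list(layers = best_layers, activation = activation, loss = best_loss)
}

mlp_predict <- function(model, X) {
  acts <- mlp_forward(model$layers, X, model$activation)
  acts[[length(acts)]]
}
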