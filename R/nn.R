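# A small, fully deterministic feed-forward network engine (ReLU hidden
# layers, softmax output, cross-entropy loss, Adam). Sized for a handful of
# radiomic features; everything is plain R matrix algebra.

mlp_init <- function(n_in, hidden, n_out, seed) {
  set.seed(seed)
  sizes <- c(n_in, hidden, n_out)
  layers <- vector("list", length(sizes) - 1)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1]),
      b = rep(0, sizes[l + 1]))
  }
  layers
}

mlp_forward <- function(layers, X, keep = FALSE) {
  acts <- list(X)
  H <- X
  nl <- length(layers)
  for (l in seq_len(nl)) {
    Z <- sweep(H %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    H <- if (l < nl) pmax(Z, 0) else Z
    if (keep) acts[[l + 1]] <- H
  }
  # softmax, numerically stable
  Z <- H - apply(H, 1, max)
  P <- exp(Z); P <- P / rowSums(P)
  if (keep) list(probs = P, acts = acts) else P
}

softmax_ce_grad <- function(P, y_onehot) (P - y_onehot) / nrow(P)

adam_new <- function(layers) lapply(layers, function(l)
  list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))

adam_update <- function(par, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mh <- st$m / (1 - beta1^t)
  vh <- st$v / (1 - beta2^t)
  list(par = par - lr * mh / (sqrt(vh) + eps), state = st)
}

mlp_train <- function(layers, X, y, Xval = NULL, yval = NULL,
                      epochs = 300, lr = 0.01, seed = 1) {
  # y: integer class index 1..K
  K <- ncol(layers[[length(layers)]]$W)
  Y <- diag(K)[y, , drop = FALSE]
  opt <- adam_new(layers)
  best <- list(loss = Inf, layers = layers)
  history <- numeric(epochs)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    fw <- mlp_forward(layers, X, keep = TRUE)
    dZ <- softmax_ce_grad(fw$probs, Y)
    nl <- length(layers)
    for (l in rev(seq_len(nl))) {
      A <- fw$acts[[l]]
      gW <- crossprod(A, dZ)
      gb <- colSums(dZ)
      if (l > 1) {
        dA <- dZ %*% t(layers[[l]]$W)
        dZ <- dA * (fw$acts[[l]] > 0)
      }
      uw <- adam_update(layers[[l]]$W, gW,
                        list(m = opt[[l]]$mW, v = opt[[l]]$vW), lr, ep)
      layers[[l]]$W <- uw$par; opt[[l]]$mW <- uw$state$m; opt[[l]]$vW <- uw$state$v
      ub <- adam_update(layers[[l]]$b, gb,
                        list(m = opt[[l]]$mb, v = opt[[l]]$vb), lr, ep)
      layers[[l]]$b <- ub$par; opt[[l]]$mb <- ub$state$m; opt[[l]]$vb <- ub$state$v
    }
    if (!is.null(Xval)) {
      Pv <- mlp_forward(layers, Xval)
      lv <- -mean(log(pmax(Pv[cbind(seq_along(yval), yval)], 1e-12)))
      history[ep] <- lv
      if (lv < best$loss) best <- list(loss = lv, layers = layers)
    }
  }
  if (is.null(Xval)) best <- list(loss = NA_real_, layers = layers)
  list(layers = best$layers, val_loss = best$loss, history = history)
}
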