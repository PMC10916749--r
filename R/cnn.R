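# Native 3D convolutional network: repeated blocks of 3x3x3 "same"
# convolution -> batch normalization -> ReLU -> 2x2x2 max pooling, then two
# fully connected layers and a softmax over the two classes. Convolutions run
# as one BLAS product per sample via im2col (src/nn_ops.cpp); training is
# minibatch Adam with batch statistics for BN and running statistics for
# inference. Everything is seeded and deterministic.

#' Configuration of the 3D CNN
#'
#' @param input_shape cubic input shape (default `c(32, 32, 32)`; volumes are
#'   centre crop/padded to it).
#' @param channels feature maps per conv block (default 8, 16, 32).
#' @param fc width of the fully connected layer before the output (default 64).
#' @param epochs training epochs (default 15).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed RNG seed for init and shuffling.
#' @return a `petrad_cnn_config` list.
#' @export
cnn_config <- function(input_shape = c(32, 32, 32), channels = c(8, 16, 32),
                       fc = 64, epochs = 15, lr = 1e-3, batch_size = 10,
                       seed = 7L) {
  stopifnot(length(input_shape) == 3, length(channels) >= 1, fc >= 2)
  structure(list(input_shape = as.integer(input_shape),
                 channels = as.integer(channels), fc = as.integer(fc),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "petrad_cnn_config")
}

cnn_init <- function(config) {
  set.seed(config$seed)
  shape <- config$input_shape
  cin <- 1L
  conv <- list()
  for (b in seq_along(config$channels)) {
    cout <- config$channels[b]
    fan <- 27L * cin
    conv[[b]] <- list(
      W = matrix(rnorm(fan * cout, sd = sqrt(2 / fan)), fan, cout),
      b = rep(0, cout),
      gamma = rep(1, cout), beta = rep(0, cout),
      running_mean = rep(0, cout), running_var = rep(1, cout))
    cin <- cout
    shape <- shape %/% 2L
  }
  flat <- prod(shape) * cin
  list(conv = conv,
       fc1 = list(W = matrix(rnorm(flat * config$fc, sd = sqrt(2 / flat)),
                             flat, config$fc), b = rep(0, config$fc)),
       fc2 = list(W = matrix(rnorm(config$fc * 2, sd = sqrt(2 / config$fc)),
                             config$fc, 2), b = rep(0, 2)),
       flat_shape = c(shape, cin))
}

# forward through all conv blocks + head for a list of 4D sample arrays;
# returns probabilities, caches for backprop, and (in training) params with
# refreshed BN running statistics
cnn_forward <- function(params, xs, training = TRUE, momentum = 0.1,
                        eps = 1e-5) {
  blocks <- vector("list", length(params$conv))
  for (bi in seq_along(params$conv)) {
    p <- params$conv[[bi]]
    dims <- dim(xs[[1]])
    cols <- lapply(xs, cpp_im2col3, k = 3L, pad = 1L)
    Zs <- lapply(cols, function(cc) sweep(cc %*% p$W, 2, p$b, `+`))
    if (training) {
      n <- length(Zs) * nrow(Zs[[1]])
      mu <- Reduce(`+`, lapply(Zs, colSums)) / n
      va <- Reduce(`+`, lapply(Zs, function(z)
        colSums(sweep(z, 2, mu)^2))) / n
      params$conv[[bi]]$running_mean <-
        (1 - momentum) * p$running_mean + momentum * mu
      params$conv[[bi]]$running_var <-
        (1 - momentum) * p$running_var + momentum * va
    } else {
      mu <- p$running_mean; va <- p$running_var
    }
    istd <- 1 / sqrt(va + eps)
    xhat <- lapply(Zs, function(z) sweep(sweep(z, 2, mu), 2, istd, `*`))
    act <- lapply(xhat, function(h)
      pmax(sweep(sweep(h, 2, p$gamma, `*`), 2, p$beta, `+`), 0))
    odim <- c(dims[1:3], ncol(p$W))
    pooled <- lapply(act, function(a) cpp_maxpool3(array(a, dim = odim)))
    blocks[[bi]] <- list(cols = cols, xhat = xhat, istd = istd, act = act,
                         argmax = lapply(pooled, `[[`, "argmax"),
                         in_dim = odim)
    xs <- lapply(pooled, `[[`, "out")
  }
  flat <- t(vapply(xs, as.vector, numeric(prod(dim(xs[[1]])))))
  H1 <- pmax(sweep(flat %*% params$fc1$W, 2, params$fc1$b, `+`), 0)
  Z2 <- sweep(H1 %*% params$fc2$W, 2, params$fc2$b, `+`)
  Zs2 <- Z2 - apply(Z2, 1, max)
  P <- exp(Zs2); P <- P / rowSums(P)
  list(probs = P, blocks = blocks, flat = flat, H1 = H1, params = params,
       pooled_dim = dim(xs[[1]]))
}

# gradients for one minibatch; y is 1/2 class index
cnn_backward <- function(params, fw, y) {
  B <- nrow(fw$probs)
  Y <- diag(2)[y, , drop = FALSE]
  dZ2 <- (fw$probs - Y) / B
  g <- list(fc2 = list(W = crossprod(fw$H1, dZ2), b = colSums(dZ2)))
  dH1 <- dZ2 %*% t(params$fc2$W) * (fw$H1 > 0)
  g$fc1 <- list(W = crossprod(fw$flat, dH1), b = colSums(dH1))
  dflat <- dH1 %*% t(params$fc1$W)
  dxs <- lapply(seq_len(B), function(i)
    array(dflat[i, ], dim = fw$pooled_dim))
  g$conv <- vector("list", length(params$conv))
  for (bi in rev(seq_along(params$conv))) {
    blk <- fw$blocks[[bi]]
    p <- params$conv[[bi]]
    # through max pooling
    dact <- lapply(seq_along(dxs), function(i)
      cpp_maxpool3_backward(dxs[[i]], blk$argmax[[i]], blk$in_dim))
    V <- prod(blk$in_dim[1:3]); C <- blk$in_dim[4]
    dact <- lapply(dact, function(a) matrix(a, V, C))
    # through ReLU
    dact <- lapply(seq_along(dact), function(i) dact[[i]] * (blk$act[[i]] > 0))
    # through batch norm
    dgamma <- Reduce(`+`, lapply(seq_along(dact), function(i)
      colSums(dact[[i]] * blk$xhat[[i]])))
    dbeta <- Reduce(`+`, lapply(dact, colSums))
    n <- length(dact) * V
    m1 <- dbeta / n    # per-channel mean of the incoming gradient
    m2 <- dgamma / n   # per-channel mean of gradient * xhat
    dZ <- lapply(seq_along(dact), function(i)
      sweep(dact[[i]] - matrix(m1, V, C, byrow = TRUE) -
              sweep(blk$xhat[[i]], 2, m2, `*`),
            2, p$gamma * blk$istd, `*`))
    gW <- Reduce(`+`, lapply(seq_along(dZ), function(i)
      crossprod(blk$cols[[i]], dZ[[i]])))
    gb <- Reduce(`+`, lapply(dZ, colSums))
    g$conv[[bi]] <- list(W = gW, b = gb, gamma = dgamma, beta = dbeta)
    if (bi > 1) {
      prev_dim <- c(blk$in_dim[1:3], ncol(params$conv[[bi - 1]]$W))
      dxs <- lapply(dZ, function(dz)
        array(cpp_col2im3(dz %*% t(p$W), as.integer(prev_dim), 3L, 1L),
              dim = prev_dim))
    }
  }
  g
}

#' Train the 3D CNN on a set of volumes
#'
#' Low-level trainer: volumes are centre crop/padded to `config$input_shape`,
#' training runs minibatch Adam with early selection of the best
#' validation-loss parameters.
#'
#' @param volumes list of 3D arrays.
#' @param y integer class labels (1 or 2), one per volume.
#' @param train_idx,val_idx index vectors into `volumes`.
#' @param config a [cnn_config()].
#' @return list with `params`, `config`, `val_loss`, `history`.
#' @keywords internal
cnn_train <- function(volumes, y, train_idx, val_idx, config = cnn_config()) {
  xs <- lapply(volumes, function(v)
    array(crop_pad(v, config$input_shape), dim = c(config$input_shape, 1L)))
  params <- cnn_init(config)
  zero_state <- function(p) list(m = p * 0, v = p * 0)
  opt <- list(conv = lapply(params$conv, function(cp)
    lapply(cp[c("W", "b", "gamma", "beta")], zero_state)),
    fc1 = lapply(params$fc1, zero_state),
    fc2 = lapply(params$fc2, zero_state))
  best <- list(loss = Inf, params = params)
  history <- numeric(config$epochs)
  tstep <- 0
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(train_idx)
    nb <- ceiling(length(ord) / config$batch_size)
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size,
                                                       length(ord))]
      if (length(idx) < 2) next  # BN needs more than one sample
      fw <- cnn_forward(params, xs[idx], training = TRUE)
      params <- fw$params       # refreshed running stats
      gr <- cnn_backward(params, fw, y[idx])
      tstep <- tstep + 1
      for (bi in seq_along(params$conv))
        for (nm in c("W", "b", "gamma", "beta")) {
          u <- adam_update(params$conv[[bi]][[nm]], gr$conv[[bi]][[nm]],
                           opt$conv[[bi]][[nm]], config$lr, tstep)
          params$conv[[bi]][[nm]] <- u$par
          opt$conv[[bi]][[nm]] <- u$state
        }
      for (nm in c("fc1", "fc2"))
        for (pp in c("W", "b")) {
          u <- adam_update(params[[nm]][[pp]], gr[[nm]][[pp]],
                           opt[[nm]][[pp]], config$lr, tstep)
          params[[nm]][[pp]] <- u$par
          opt[[nm]][[pp]] <- u$state
        }
    }
    if (length(val_idx)) {
      Pv <- cnn_predict_probs(list(params = params, config = config),
                              volumes[val_idx])
      lv <- -mean(log(pmax(Pv[cbind(seq_along(val_idx), y[val_idx])], 1e-12)))
      history[ep] <- lv
      if (lv < best$loss) best <- list(loss = lv, params = params)
    } else best <- list(loss = NA_real_, params = params)
  }
  list(params = best$params, config = config, val_loss = best$loss,
       history = history)
}

# class probabilities (rows sum to 1) in inference mode
cnn_predict_probs <- function(model, volumes) {
  xs <- lapply(volumes, function(v)
    array(crop_pad(v, model$config$input_shape),
          dim = c(model$config$input_shape, 1L)))
  out <- matrix(NA_real_, length(xs), 2)
  bs <- 16L
  for (s in seq(1, length(xs), by = bs)) {
    idx <- s:min(s + bs - 1L, length(xs))
    fw <- cnn_forward(model$params, xs[idx], training = FALSE)
    out[idx, ] <- fw$probs
  }
  out
}
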