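# A compact native LSTM classifier: single LSTM layer -> dropout -> dense
# ReLU -> dense softmax, trained with Adam on categorical cross-entropy.
# Written in plain R matrix algebra; gradients are exact BPTT and are
# verified against finite differences in the test suite.
#
# Gate column order inside the stacked weight matrices: i, f, g, o.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

lstm_init <- function(n_features, units, dense_units, n_classes, seed) {
  set.seed(seed)
  b <- rep(0, 4 * units)
  b[(units + 1):(2 * units)] <- 1 # forget-gate bias starts open
  list(Wx = glorot(n_features, 4 * units),
       Wh = glorot(units, 4 * units),
       b = b,
       W1 = glorot(units, dense_units), b1 = rep(0, dense_units),
       W2 = glorot(dense_units, n_classes), b2 = rep(0, n_classes))
}

# Xlist: length-T list of B x D matrices
lstm_forward <- function(params, Xlist, dropout_mask = NULL) {
  U <- ncol(params$Wh)
  units <- U / 4
  B <- nrow(Xlist[[1]])
  h <- matrix(0, B, units)
  cc <- matrix(0, B, units)
  steps <- vector("list", length(Xlist))
  idx_i <- 1:units; idx_f <- units + idx_i; idx_g <- 2 * units + idx_i
  idx_o <- 3 * units + idx_i
  for (t in seq_along(Xlist)) {
    z <- Xlist[[t]] %*% params$Wx + h %*% params$Wh +
      matrix(params$b, B, U, byrow = TRUE)
    i <- sigmoid(z[, idx_i, drop = FALSE])
    f <- sigmoid(z[, idx_f, drop = FALSE])
    g <- tanh(z[, idx_g, drop = FALSE])
    o <- sigmoid(z[, idx_o, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    steps[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev, tc = tc,
                       h_prev = h_prev, x = Xlist[[t]])
  }
  h_drop <- if (is.null(dropout_mask)) h else h * dropout_mask
  z1 <- h_drop %*% params$W1 + matrix(params$b1, B, length(params$b1),
                                      byrow = TRUE)
  a1 <- pmax(z1, 0)
  z2 <- a1 %*% params$W2 + matrix(params$b2, B, length(params$b2),
                                  byrow = TRUE)
  probs <- softmax_rows(z2)
  list(probs = probs, steps = steps, h = h, h_drop = h_drop, z1 = z1, a1 = a1)
}

# y: integer class labels 1..C; returns list(loss, grads)
lstm_backward <- function(params, fwd, y, dropout_mask = NULL) {
  B <- nrow(fwd$probs)
  C <- ncol(fwd$probs)
  Y <- matrix(0, B, C)
  Y[cbind(seq_len(B), y)] <- 1
  loss <- -mean(log(pmax(fwd$probs[cbind(seq_len(B), y)], 1e-12)))

  dZ2 <- (fwd$probs - Y) / B
  gW2 <- crossprod(fwd$a1, dZ2)
  gb2 <- colSums(dZ2)
  dA1 <- tcrossprod(dZ2, params$W2)
  dZ1 <- dA1 * (fwd$z1 > 0)
  gW1 <- crossprod(fwd$h_drop, dZ1)
  gb1 <- colSums(dZ1)
  dHdrop <- tcrossprod(dZ1, params$W1)
  dh <- if (is.null(dropout_mask)) dHdrop else dHdrop * dropout_mask

  units <- ncol(params$Wh) / 4
  idx_i <- 1:units; idx_f <- units + idx_i; idx_g <- 2 * units + idx_i
  idx_o <- 3 * units + idx_i
  gWx <- 0 * params$Wx; gWh <- 0 * params$Wh; gb <- 0 * params$b
  dc <- matrix(0, B, units)
  for (t in rev(seq_along(fwd$steps))) {
    st <- fwd$steps[[t]]
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc <- dc * st$f
    dZ <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    gWx <- gWx + crossprod(st$x, dZ)
    gWh <- gWh + crossprod(st$h_prev, dZ)
    gb <- gb + colSums(dZ)
    dh <- tcrossprod(dZ, params$Wh)
  }
  list(loss = loss,
       grads = list(Wx = gWx, Wh = gWh, b = gb,
                    W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

adam_init <- function(params) {
  list(m = map(params, function(p) 0 * p),
       v = map(params, function(p) 0 * p),
       t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# values: list of WS x D matrices; returns length-T list of B x D matrices
stack_timesteps <- function(values, idx, scale_mu, scale_sd) {
  ws <- nrow(values[[idx[1]]])
  arr <- array(unlist(values[idx], use.names = FALSE),
               dim = c(ws, ncol(values[[idx[1]]]), length(idx)))
  map(seq_len(ws), function(t) {
    m <- t(arr[t, , , drop = TRUE])
    if (length(idx) == 1) m <- matrix(arr[t, , 1], nrow = 1)
    sweep(sweep(m, 2, scale_mu, "-"), 2, scale_sd, "/")
  })
}

lstm_train <- function(values, y, n_classes, units = 60, dense_units = 60,
                       dropout = 0.5, batch_size = 64, epochs = 40,
                       lr = 1e-3, seed = 42) {
  D <- ncol(values[[1]])
  flat <- do.call(rbind, values)
  scale_mu <- colMeans(flat)
  scale_sd <- pmax(apply(flat, 2, stats::sd), 1e-6)
  params <- lstm_init(D, units, dense_units, n_classes,
                      seed = derive_seed(seed, 17))
  state <- adam_init(params)
  n <- length(values)
  log <- tibble(epoch = integer(), loss = double(), accuracy = double())
  for (ep in seq_len(epochs)) {
    set.seed(derive_seed(seed, 29, ep))
    ord <- sample(n)
    batch_losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xlist <- stack_timesteps(values, idx, scale_mu, scale_sd)
      mask <- if (dropout > 0) {
        matrix(stats::rbinom(length(idx) * units, 1, 1 - dropout),
               length(idx), units) / (1 - dropout)
      } else NULL
      fwd <- lstm_forward(params, Xlist, dropout_mask = mask)
      bwd <- lstm_backward(params, fwd, y[idx], dropout_mask = mask)
      upd <- adam_step(params, bwd$grads, state, lr = lr)
      params <- upd$params
      state <- upd$state
      batch_losses <- c(batch_losses, bwd$loss)
    }
    acc <- mean(lstm_predict(list(params = params, scale_mu = scale_mu,
                                  scale_sd = scale_sd), values)$label == y)
    log <- bind_rows(log, tibble(epoch = ep, loss = mean(batch_losses),
                                 accuracy = acc))
  }
  list(params = params, scale_mu = scale_mu, scale_sd = scale_sd,
       training_log = log)
}

lstm_predict <- function(fit, values, chunk = 256L) {
  n <- length(values)
  probs <- NULL
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    Xlist <- stack_timesteps(values, idx, fit$scale_mu, fit$scale_sd)
    fwd <- lstm_forward(fit$params, Xlist)
    probs <- rbind(probs, fwd$probs)
  }
  list(probs = probs, label = max.col(probs, ties.method = "first"))
}
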