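# Neural-network primitives (forward + exact backward passes), implemented
# natively with BLAS-backed matrix algebra.  Conventions:
#  * batched sequence tensors are R arrays (N, T, D); merging the first two
#    dims via dim<- is a free reshape in column-major layout, so row
#    n + N*(t-1) of the (N*T, D) matrix is sample (n, t)
#  * conv weights are stored as (kernel*in_channels, filters) matrices with
#    column index (tap j, channel c) -> j + k*(c-1)
#  * LSTM gate order along the 4H axis is i, f, g (candidate), o

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- dense -----------------------------------------------------------

dense_fwd <- function(X, W, b) {
  out <- X %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = out, cache = list(X = X))
}

dense_bwd <- function(dout, W, cache) {
  list(dX = dout %*% t(W),
       dW = crossprod(cache$X, dout),
       db = colSums(dout))
}

## ---- relu / dropout --------------------------------------------------

relu_fwd <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_bwd <- function(dout, cache) dout * cache

dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, cache = NULL))
  keep <- 1 - p
  mask <- (matrix(stats::runif(length(X)), nrow(X)) < keep) / keep
  list(out = X * mask, cache = mask)
}
dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

## ---- batch normalization (per column) --------------------------------

bn_fwd <- function(X, gamma, beta, state, training, momentum = 0.9,
                   eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu)
    var <- colMeans(xc^2)
    istd <- 1 / sqrt(var + eps)
    xhat <- sweep(xc, 2L, istd, "*")
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var  <- momentum * state$var  + (1 - momentum) * var
    cache <- list(xhat = xhat, istd = istd, gamma = gamma)
  } else {
    xhat <- sweep(sweep(X, 2L, state$mean), 2L,
                  1 / sqrt(state$var + eps), "*")
    cache <- NULL
  }
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, cache = cache, state = state)
}

bn_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  n <- nrow(dout)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, cache$gamma, "*")
  # dX = istd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  dX <- sweep(
    n * dxhat -
      matrix(colSums(dxhat), n, ncol(dout), byrow = TRUE) -
      xhat * matrix(dgamma, n, ncol(dout), byrow = TRUE),
    2L, cache$istd / n, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

bn_state_new <- function(f) list(mean = numeric(f), var = rep(1, f))

## ---- 1-D convolution (valid padding) via im2col ----------------------

# X: (N, L, Cin) -> patches matrix (N*Lout, k*Cin)
im2col <- function(X, k, s, lout) {
  n <- dim(X)[1L]; cin <- dim(X)[3L]
  P <- array(0, dim = c(n, lout, k * cin))
  for (p in seq_len(lout)) {
    sl <- X[, ((p - 1L) * s + 1L):((p - 1L) * s + k), , drop = FALSE]
    dim(sl) <- c(n, k * cin)
    P[, p, ] <- sl
  }
  dim(P) <- c(n * lout, k * cin)
  P
}

col2im <- function(dP, dimX, k, s, lout) {
  n <- dimX[1L]; cin <- dimX[3L]
  dX <- array(0, dim = dimX)
  dim(dP) <- c(n, lout, k * cin)
  for (p in seq_len(lout)) {
    sl <- dP[, p, ]
    dim(sl) <- c(n, k, cin)
    idx <- ((p - 1L) * s + 1L):((p - 1L) * s + k)
    dX[, idx, ] <- dX[, idx, , drop = FALSE] + sl
  }
  dX
}

conv_out_len <- function(l, k, s, strict = TRUE) {
  if (k > l) stop("conv1d: kernel (", k, ") longer than input (", l, ")")
  if (strict && (l - k) %% s != 0L)
    stop("conv1d: input length ", l, " with kernel ", k, " and stride ", s,
         " leaves a non-integer output length")
  (l - k) %/% s + 1L
}

# X: (N, L, Cin); W: (k*Cin, F); returns (N, Lout, F)
conv1d_fwd <- function(X, W, b, k, s) {
  lout <- conv_out_len(dim(X)[2L], k, s)
  P <- im2col(X, k, s, lout)
  out <- sweep(P %*% W, 2L, b, "+")
  cache <- list(P = P, dimX = dim(X), k = k, s = s, lout = lout)
  dim(out) <- c(dim(X)[1L], lout, length(b))
  list(out = out, cache = cache)
}

conv1d_bwd <- function(dout, W, cache) {
  dim(dout) <- c(cache$dimX[1L] * cache$lout, ncol(W))
  dW <- crossprod(cache$P, dout)
  db <- colSums(dout)
  dX <- col2im(dout %*% t(W), cache$dimX, cache$k, cache$s, cache$lout)
  list(dX = dX, dW = dW, db = db)
}

## ---- LSTM (batched, full-sequence output) ----------------------------

# X: (N, T, D); Wx: (D, 4H); Wh: (H, 4H); b: (4H)
lstm_fwd <- function(X, Wx, Wh, b) {
  n <- dim(X)[1L]; tt <- dim(X)[2L]; h <- ncol(Wh) / 4L
  H <- array(0, dim = c(n, tt, h))
  gi <- array(0, dim = c(n, tt, h)); gf <- gi; gg <- gi; go <- gi
  cs <- array(0, dim = c(n, tt, h)); tc <- cs
  hp <- matrix(0, n, h); cp <- matrix(0, n, h)
  for (t in seq_len(tt)) {
    xt <- matrix(X[, t, ], n, dim(X)[3L])
    Z <- sweep(xt %*% Wx + hp %*% Wh, 2L, b, "+")
    i <- sigmoid(Z[, 1:h, drop = FALSE])
    f <- sigmoid(Z[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(Z[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- sigmoid(Z[, (3 * h + 1):(4 * h), drop = FALSE])
    cc <- f * cp + i * g
    tcc <- tanh(cc)
    hp2 <- o * tcc
    gi[, t, ] <- i; gf[, t, ] <- f; gg[, t, ] <- g; go[, t, ] <- o
    cs[, t, ] <- cc; tc[, t, ] <- tcc; H[, t, ] <- hp2
    hp <- hp2; cp <- cc
  }
  list(out = H,
       cache = list(X = X, gi = gi, gf = gf, gg = gg, go = go,
                    cs = cs, tc = tc, H = H, h = h))
}

lstm_bwd <- function(dH, Wx, Wh, cache) {
  X <- cache$X
  n <- dim(X)[1L]; tt <- dim(X)[2L]; d <- dim(X)[3L]; h <- cache$h
  dX <- array(0, dim = dim(X))
  dWx <- matrix(0, d, 4L * h); dWh <- matrix(0, h, 4L * h)
  db <- numeric(4L * h)
  dh_next <- matrix(0, n, h); dc_next <- matrix(0, n, h)
  for (t in rev(seq_len(tt))) {
    dh <- matrix(dH[, t, ], n, h) + dh_next
    i <- matrix(cache$gi[, t, ], n, h); f <- matrix(cache$gf[, t, ], n, h)
    g <- matrix(cache$gg[, t, ], n, h); o <- matrix(cache$go[, t, ], n, h)
    tcc <- matrix(cache$tc[, t, ], n, h)
    cprev <- if (t > 1L) matrix(cache$cs[, t - 1L, ], n, h)
             else matrix(0, n, h)
    hprev <- if (t > 1L) matrix(cache$H[, t - 1L, ], n, h)
             else matrix(0, n, h)
    dc <- dc_next + dh * o * (1 - tcc^2)
    dZ <- cbind(dc * g * i * (1 - i),
                dc * cprev * f * (1 - f),
                dc * i * (1 - g^2),
                dh * tcc * o * (1 - o))
    xt <- matrix(X[, t, ], n, d)
    dWx <- dWx + crossprod(xt, dZ)
    dWh <- dWh + crossprod(hprev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(Wx)
    dh_next <- dZ %*% t(Wh)
    dc_next <- dc * f
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# bidirectional LSTM: forward + time-reversed backward pass, concatenated
bilstm_fwd <- function(X, Wx_f, Wh_f, b_f, Wx_b, Wh_b, b_b) {
  n <- dim(X)[1L]; tt <- dim(X)[2L]
  fw <- lstm_fwd(X, Wx_f, Wh_f, b_f)
  Xr <- X[, rev(seq_len(tt)), , drop = FALSE]
  bw <- lstm_fwd(Xr, Wx_b, Wh_b, b_b)
  Hb <- bw$out[, rev(seq_len(tt)), , drop = FALSE]
  h <- dim(fw$out)[3L]
  out <- array(0, dim = c(n, tt, 2L * h))
  out[, , 1:h] <- fw$out
  out[, , (h + 1):(2 * h)] <- Hb
  list(out = out, cache = list(fw = fw$cache, bw = bw$cache, h = h, tt = tt))
}

bilstm_bwd <- function(dOut, Wx_f, Wh_f, Wx_b, Wh_b, cache) {
  h <- cache$h; tt <- cache$tt
  dHf <- dOut[, , 1:h, drop = FALSE]
  dHb <- dOut[, , (h + 1):(2 * h), drop = FALSE]
  gf <- lstm_bwd(dHf, Wx_f, Wh_f, cache$fw)
  gb <- lstm_bwd(dHb[, rev(seq_len(tt)), , drop = FALSE], Wx_b, Wh_b,
                 cache$bw)
  dX <- gf$dX + gb$dX[, rev(seq_len(tt)), , drop = FALSE]
  list(dX = dX, f = gf, b = gb)
}

## ---- softmax + cross-entropy -----------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Cross-entropy loss
#'
#' Mean per-sample categorical cross-entropy `-sum(y * log(p))` with a
#' probability floor of `1e-12` before the logarithm.  The mean (rather
#' than batch-sum) variant is reported so the loss is batch-size invariant;
#' the two differ by the constant factor `M` (the batch size).
#'
#' @param predicted_probs `N x K` matrix, each row a distribution.
#' @param true_onehot `N x K` one-hot matrix (or a length-`N` integer vector
#'   of 1-based class labels).
#' @return scalar mean loss.
#' @export
cross_entropy_loss <- function(predicted_probs, true_onehot) {
  if (is.vector(true_onehot) && !is.matrix(true_onehot))
    true_onehot <- onehot(true_onehot, ncol(predicted_probs))
  if (!all(dim(predicted_probs) == dim(true_onehot)))
    stop("cross_entropy_loss: shape mismatch")
  p <- pmax(predicted_probs, 1e-12)
  -mean(rowSums(true_onehot * log(p)))
}

onehot <- function(labels, k) {
  n <- length(labels)
  if (any(labels < 1L | labels > k))
    stop("onehot: labels must lie in 1..", k)
  m <- matrix(0, n, k)
  m[cbind(seq_len(n), labels)] <- 1
  m
}

## ---- parameter initialization / Adam ---------------------------------

glorot <- function(nin, nout, dims = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# LSTM parameter block; forget-gate bias starts at 1
lstm_params <- function(d, h) {
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1
  list(Wx = glorot(d, 4 * h), Wh = glorot(h, 4 * h), b = b)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
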