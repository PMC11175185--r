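#' Architecture specification for the dual-stream classifier
#'
#' Declarative description of the fusion network.  Under the DB1 defaults
#' the shape arithmetic reproduces the published layer geometry: feature
#' stream 5 -> 3 -> 2 (kernels 3 and 2, stride 1, valid padding), raw
#' stream 20 -> 10 -> 5 (kernel 2, stride 2, valid padding), per-window
#' flattened widths 512 and 1280, fused width 1792, Bi-LSTM head width
#' 200 (100 units per direction, both layers returning full sequences),
#' dense 512, softmax over `n_classes` per window.
#'
#' All convolution output lengths follow `L_out = (L - k)/s + 1` and must
#' be integers; otherwise construction fails.
#'
#' @param nf windows per trial (25 for 200-ms windows over 500 samples).
#' @param window_samples samples per raw window (20).
#' @param n_channels electrode count (10 for DB1).
#' @param n_classes gesture classes (52 for DB1).
#' @param conv_filters filters per convolution (default 256).
#' @param feature_kernels,feature_strides per-stage kernel/stride of the
#'   feature stream (defaults `c(3, 2)` / `c(1, 1)`).
#' @param raw_kernels,raw_strides per-stage kernel/stride of the raw stream
#'   (defaults `c(2, 2)` / `c(2, 2)`).
#' @param inner_units units of the recurrent layer between the raw-stream
#'   convolutions (default 256).
#' @param bilstm_units units per direction of each Bi-LSTM layer (default
#'   100).
#' @param dense_units width of the penultimate dense layer (default 512).
#' @param dropout_conv,dropout_dense dropout rates after conv blocks and
#'   after the dense block.
#' @param l2 L2 penalty coefficient applied to conv and dense kernels.
#' @param bn_eps,bn_momentum batch-normalization epsilon and momentum.
#' @param n_features number of time-domain features (5).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(nf = 25L, window_samples = 20L, n_channels = 10L,
                       n_classes = 52L, conv_filters = 256L,
                       feature_kernels = c(3L, 2L),
                       feature_strides = c(1L, 1L),
                       raw_kernels = c(2L, 2L), raw_strides = c(2L, 2L),
                       inner_units = 256L, bilstm_units = 100L,
                       dense_units = 512L, dropout_conv = 0.3,
                       dropout_dense = 0.5, l2 = 0.01,
                       bn_eps = 1e-5, bn_momentum = 0.9,
                       n_features = 5L) {
  spec <- structure(
    list(nf = as.integer(nf), window_samples = as.integer(window_samples),
         n_channels = as.integer(n_channels),
         n_classes = as.integer(n_classes),
         conv_filters = as.integer(conv_filters),
         feature_kernels = as.integer(feature_kernels),
         feature_strides = as.integer(feature_strides),
         raw_kernels = as.integer(raw_kernels),
         raw_strides = as.integer(raw_strides),
         inner_units = as.integer(inner_units),
         bilstm_units = as.integer(bilstm_units),
         dense_units = as.integer(dense_units),
         dropout_conv = dropout_conv, dropout_dense = dropout_dense,
         l2 = l2, bn_eps = bn_eps, bn_momentum = bn_momentum,
         n_features = as.integer(n_features)),
    class = "model_spec")
  spec_lengths(spec)  # validates the conv arithmetic eagerly
  spec
}

# per-stage output lengths of both streams (errors if non-integer)
spec_lengths <- function(spec) {
  fl <- spec$n_features
  flen <- integer(0)
  for (i in seq_along(spec$feature_kernels)) {
    fl <- conv_out_len(fl, spec$feature_kernels[i], spec$feature_strides[i])
    flen <- c(flen, fl)
  }
  rl <- spec$window_samples
  rlen <- integer(0)
  for (i in seq_along(spec$raw_kernels)) {
    rl <- conv_out_len(rl, spec$raw_kernels[i], spec$raw_strides[i])
    rlen <- c(rlen, rl)
  }
  list(feature = flen, raw = rlen,
       feature_flat = fl * spec$conv_filters,
       raw_flat = rl * spec$conv_filters,
       fused = (fl + rl) * spec$conv_filters)
}

shp <- function(...) paste0("(", paste(c(...), collapse = ", "), ")")

#' Build the dual-stream fusion model
#'
#' Realizes the architecture of [model_spec()]: two per-window encoders
#' (time-distributed over the window axis) — a feature stream of two
#' conv+BN+ReLU+dropout stages, and a raw stream of conv, inner LSTM over
#' the within-window sample axis, conv — flattened per window, fused by
#' concatenation, then two bidirectional LSTM layers (full sequences), a
#' per-window dense+BN+ReLU+dropout block and a per-window softmax head.
#' Weights are Glorot-initialized from the current RNG state (seed before
#' calling for reproducibility); forget-gate biases start at 1.
#'
#' @param spec a [model_spec()].
#' @return object of class `fusion_model` with `spec`, `params`,
#'   `bn_states`, `graph` (declared layer table) and `type = "dual"`.
#' @export
build_dual_stream <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  L <- spec_lengths(spec)
  Fm <- spec$conv_filters; C <- spec$n_channels; U <- spec$inner_units
  H <- spec$bilstm_units; D <- L$fused
  p <- list(
    fc1_W = glorot(spec$feature_kernels[1] * C, Fm),
    fc1_b = numeric(Fm),
    fc2_W = glorot(spec$feature_kernels[2] * Fm, Fm),
    fc2_b = numeric(Fm),
    fbn1_gamma = rep(1, Fm), fbn1_beta = numeric(Fm),
    fbn2_gamma = rep(1, Fm), fbn2_beta = numeric(Fm),
    rc1_W = glorot(spec$raw_kernels[1] * C, Fm),
    rc1_b = numeric(Fm),
    rbn1_gamma = rep(1, Fm), rbn1_beta = numeric(Fm),
    rc2_W = glorot(spec$raw_kernels[2] * U, Fm),
    rc2_b = numeric(Fm),
    rbn2_gamma = rep(1, Fm), rbn2_beta = numeric(Fm),
    d1_W = glorot(2 * H, spec$dense_units), d1_b = numeric(spec$dense_units),
    dbn_gamma = rep(1, spec$dense_units), dbn_beta = numeric(spec$dense_units),
    d2_W = glorot(spec$dense_units, spec$n_classes),
    d2_b = numeric(spec$n_classes))
  rl <- lstm_params(Fm, U)
  p$rlstm_Wx <- rl$Wx; p$rlstm_Wh <- rl$Wh; p$rlstm_b <- rl$b
  for (i in 1:2) {
    din <- if (i == 1) D else 2 * H
    for (dir in c("f", "b")) {
      bl <- lstm_params(din, H)
      p[[paste0("bl", i, "_Wx", dir)]] <- bl$Wx
      p[[paste0("bl", i, "_Wh", dir)]] <- bl$Wh
      p[[paste0("bl", i, "_b", dir)]] <- bl$b
    }
  }
  bn_states <- list(fbn1 = bn_state_new(Fm), fbn2 = bn_state_new(Fm),
                    rbn1 = bn_state_new(Fm), rbn2 = bn_state_new(Fm),
                    dbn = bn_state_new(spec$dense_units))
  nf <- spec$nf
  graph <- data.frame(
    layer = c("input_feature", "input_raw", "conv1d_feature_1",
              "conv1d_raw_1", "lstm_raw", "conv1d_feature_2",
              "conv1d_raw_2", "flatten_feature", "flatten_raw",
              "concatenate", "bilstm_1", "bilstm_2", "flatten",
              "dense_1", "dense_2"),
    shape = c(shp(nf, spec$n_features, C), shp(nf, spec$window_samples, C),
              shp(nf, L$feature[1], Fm), shp(nf, L$raw[1], Fm),
              shp(nf, L$raw[1], U), shp(nf, L$feature[2], Fm),
              shp(nf, L$raw[2], Fm), shp(nf, L$feature_flat),
              shp(nf, L$raw_flat), shp(nf, L$fused),
              shp(nf, 2 * H), shp(nf, 2 * H), shp(nf, 2 * H),
              shp(nf, spec$dense_units), shp(nf, spec$n_classes)),
    stringsAsFactors = FALSE)
  structure(list(spec = spec, params = p, bn_states = bn_states,
                 graph = graph, type = "dual"),
            class = "fusion_model")
}

#' Build the single-stream ablation model
#'
#' The raw windows pass through one conv+BN+ReLU+dropout stage only (no
#' feature stream, no inner recurrent layer, no concatenation) and feed the
#' same Bi-LSTM / dense head as the dual-stream model.
#'
#' @param spec a [model_spec()].
#' @return a `fusion_model` with `type = "single"`.
#' @export
build_single_stream <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  Fm <- spec$conv_filters; C <- spec$n_channels; H <- spec$bilstm_units
  l1 <- conv_out_len(spec$window_samples, spec$raw_kernels[1],
                     spec$raw_strides[1])
  D <- l1 * Fm
  p <- list(
    rc1_W = glorot(spec$raw_kernels[1] * C, Fm), rc1_b = numeric(Fm),
    rbn1_gamma = rep(1, Fm), rbn1_beta = numeric(Fm),
    d1_W = glorot(2 * H, spec$dense_units), d1_b = numeric(spec$dense_units),
    dbn_gamma = rep(1, spec$dense_units), dbn_beta = numeric(spec$dense_units),
    d2_W = glorot(spec$dense_units, spec$n_classes),
    d2_b = numeric(spec$n_classes))
  for (i in 1:2) {
    din <- if (i == 1) D else 2 * H
    for (dir in c("f", "b")) {
      bl <- lstm_params(din, H)
      p[[paste0("bl", i, "_Wx", dir)]] <- bl$Wx
      p[[paste0("bl", i, "_Wh", dir)]] <- bl$Wh
      p[[paste0("bl", i, "_b", dir)]] <- bl$b
    }
  }
  bn_states <- list(rbn1 = bn_state_new(Fm),
                    dbn = bn_state_new(spec$dense_units))
  nf <- spec$nf
  graph <- data.frame(
    layer = c("input_raw", "conv1d_raw_1", "flatten_raw", "bilstm_1",
              "bilstm_2", "flatten", "dense_1", "dense_2"),
    shape = c(shp(nf, spec$window_samples, C), shp(nf, l1, Fm),
              shp(nf, D), shp(nf, 2 * H), shp(nf, 2 * H), shp(nf, 2 * H),
              shp(nf, spec$dense_units), shp(nf, spec$n_classes)),
    stringsAsFactors = FALSE)
  structure(list(spec = spec, params = p, bn_states = bn_states,
                 graph = graph, type = "single"),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model: %s stream> %d parameters\n", x$type,
              count_params(x)))
  print(x$graph, row.names = FALSE)
  invisible(x)
}

#' Trainable parameter count of a model
#' @param model a `fusion_model`.
#' @return integer count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# forward pass.  Xf: (B, Nf, 5, C) or NULL for single stream;
# Xr: (B, Nf, W, C).  Returns probs (B, Nf, K) + cache of every
# intermediate needed for the backward pass, plus realized shapes.
model_forward <- function(model, Xf, Xr, training = FALSE) {
  spec <- model$spec; p <- model$params; st <- model$bn_states
  B <- dim(Xr)[1L]; nf <- dim(Xr)[2L]
  np <- B * nf
  shapes <- list()
  cache <- list(B = B, nf = nf)
  conv_block <- function(X, Wn, bn_name, k, s) {
    cv <- conv1d_fwd(X, p[[paste0(Wn, "_W")]], p[[paste0(Wn, "_b")]], k, s)
    lout <- dim(cv$out)[2L]; fm <- dim(cv$out)[3L]
    m <- cv$out; dim(m) <- c(np * lout, fm)
    bn <- bn_fwd(m, p[[paste0(bn_name, "_gamma")]],
                 p[[paste0(bn_name, "_beta")]], st[[bn_name]], training,
                 spec$bn_momentum, spec$bn_eps)
    st[[bn_name]] <<- bn$state
    rl <- relu_fwd(bn$out)
    dp <- dropout_fwd(rl$out, spec$dropout_conv, training)
    out <- dp$out; dim(out) <- c(np, lout, fm)
    list(out = out,
         cache = list(conv = cv$cache, bn = bn$cache, relu = rl$cache,
                      drop = dp$cache, lout = lout, fm = fm))
  }

  if (model$type == "dual") {
    Xfm <- Xf; dim(Xfm) <- c(np, dim(Xf)[3L], dim(Xf)[4L])
    shapes$input_feature <- dim(Xf)[2:4]
    f1 <- conv_block(Xfm, "fc1", "fbn1",
                     spec$feature_kernels[1], spec$feature_strides[1])
    shapes$conv1d_feature_1 <- c(nf, dim(f1$out)[2:3])
    f2 <- conv_block(f1$out, "fc2", "fbn2",
                     spec$feature_kernels[2], spec$feature_strides[2])
    shapes$conv1d_feature_2 <- c(nf, dim(f2$out)[2:3])
    ff <- f2$out; dim(ff) <- c(np, prod(dim(f2$out)[2:3]))
    shapes$flatten_feature <- c(nf, ncol(ff))
    cache$f1 <- f1$cache; cache$f2 <- f2$cache
    cache$dim_f2 <- dim(f2$out)
  }

  Xrm <- Xr; dim(Xrm) <- c(np, dim(Xr)[3L], dim(Xr)[4L])
  shapes$input_raw <- dim(Xr)[2:4]
  r1 <- conv_block(Xrm, "rc1", "rbn1", spec$raw_kernels[1],
                   spec$raw_strides[1])
  shapes$conv1d_raw_1 <- c(nf, dim(r1$out)[2:3])
  cache$r1 <- r1$cache

  if (model$type == "dual") {
    rl <- lstm_fwd(r1$out, p$rlstm_Wx, p$rlstm_Wh, p$rlstm_b)
    shapes$lstm_raw <- c(nf, dim(rl$out)[2:3])
    cache$rlstm <- rl$cache
    r2 <- conv_block(rl$out, "rc2", "rbn2", spec$raw_kernels[2],
                     spec$raw_strides[2])
    shapes$conv1d_raw_2 <- c(nf, dim(r2$out)[2:3])
    cache$r2 <- r2$cache
    cache$dim_r2 <- dim(r2$out)
    rf <- r2$out; dim(rf) <- c(np, prod(dim(r2$out)[2:3]))
    shapes$flatten_raw <- c(nf, ncol(rf))
    fused <- cbind(ff, rf)
    shapes$concatenate <- c(nf, ncol(fused))
    cache$split <- ncol(ff)
  } else {
    fused <- r1$out; dim(fused) <- c(np, prod(dim(r1$out)[2:3]))
    shapes$flatten_raw <- c(nf, ncol(fused))
    cache$dim_r1 <- dim(r1$out)
  }

  seqin <- fused; dim(seqin) <- c(B, nf, ncol(fused))
  b1 <- bilstm_fwd(seqin, p$bl1_Wxf, p$bl1_Whf, p$bl1_bf,
                   p$bl1_Wxb, p$bl1_Whb, p$bl1_bb)
  shapes$bilstm_1 <- c(nf, dim(b1$out)[3L])
  b2 <- bilstm_fwd(b1$out, p$bl2_Wxf, p$bl2_Whf, p$bl2_bf,
                   p$bl2_Wxb, p$bl2_Whb, p$bl2_bb)
  shapes$bilstm_2 <- c(nf, dim(b2$out)[3L])
  shapes$flatten <- shapes$bilstm_2  # shape-preserving no-op marker
  cache$b1 <- b1$cache; cache$b2 <- b2$cache

  hm <- b2$out; dim(hm) <- c(np, dim(b2$out)[3L])
  d1 <- dense_fwd(hm, p$d1_W, p$d1_b)
  bnd <- bn_fwd(d1$out, p$dbn_gamma, p$dbn_beta, st$dbn, training,
                spec$bn_momentum, spec$bn_eps)
  st$dbn <- bnd$state
  rld <- relu_fwd(bnd$out)
  dpd <- dropout_fwd(rld$out, spec$dropout_dense, training)
  shapes$dense_1 <- c(nf, ncol(dpd$out))
  d2 <- dense_fwd(dpd$out, p$d2_W, p$d2_b)
  probs <- softmax_rows(d2$out)
  shapes$dense_2 <- c(nf, ncol(probs))
  cache$d1 <- d1$cache; cache$dbn <- bnd$cache; cache$drelu <- rld$cache
  cache$ddrop <- dpd$cache; cache$d2 <- d2$cache
  cache$probs <- probs

  out <- probs; dim(out) <- c(B, nf, ncol(probs))
  model$bn_states <- st
  list(probs = out, cache = cache, shapes = shapes, model = model)
}

# backward pass from d(logits) (the (B*Nf, K) gradient of the loss w.r.t.
# the pre-softmax activations).  Returns a grads list named like params.
model_backward <- function(model, cache, dlogits) {
  spec <- model$spec; p <- model$params
  np <- cache$B * cache$nf
  g <- list()
  db2 <- dense_bwd(dlogits, p$d2_W, cache$d2)
  g$d2_W <- db2$dW; g$d2_b <- db2$db
  dx <- dropout_bwd(db2$dX, cache$ddrop)
  dx <- relu_bwd(dx, cache$drelu)
  dbn <- bn_bwd(dx, cache$dbn)
  g$dbn_gamma <- dbn$dgamma; g$dbn_beta <- dbn$dbeta
  dd1 <- dense_bwd(dbn$dX, p$d1_W, cache$d1)
  g$d1_W <- dd1$dW; g$d1_b <- dd1$db

  dseq <- dd1$dX; dim(dseq) <- c(cache$B, cache$nf, ncol(dd1$dX))
  bb2 <- bilstm_bwd(dseq, p$bl2_Wxf, p$bl2_Whf, p$bl2_Wxb, p$bl2_Whb,
                    cache$b2)
  g$bl2_Wxf <- bb2$f$dWx; g$bl2_Whf <- bb2$f$dWh; g$bl2_bf <- bb2$f$db
  g$bl2_Wxb <- bb2$b$dWx; g$bl2_Whb <- bb2$b$dWh; g$bl2_bb <- bb2$b$db
  bb1 <- bilstm_bwd(bb2$dX, p$bl1_Wxf, p$bl1_Whf, p$bl1_Wxb, p$bl1_Whb,
                    cache$b1)
  g$bl1_Wxf <- bb1$f$dWx; g$bl1_Whf <- bb1$f$dWh; g$bl1_bf <- bb1$f$db
  g$bl1_Wxb <- bb1$b$dWx; g$bl1_Whb <- bb1$b$dWh; g$bl1_bb <- bb1$b$db

  dfused <- bb1$dX; dim(dfused) <- c(np, dim(bb1$dX)[3L])

  conv_block_bwd <- function(dout3, blk, Wn, bn_name) {
    dm <- dout3; dim(dm) <- c(np * blk$lout, blk$fm)
    dm <- dropout_bwd(dm, blk$drop)
    dm <- relu_bwd(dm, blk$relu)
    dbn <- bn_bwd(dm, blk$bn)
    g[[paste0(bn_name, "_gamma")]] <<- dbn$dgamma
    g[[paste0(bn_name, "_beta")]] <<- dbn$dbeta
    dcv <- dbn$dX; dim(dcv) <- c(np, blk$lout, blk$fm)
    cb <- conv1d_bwd(dcv, p[[paste0(Wn, "_W")]], blk$conv)
    g[[paste0(Wn, "_W")]] <<- cb$dW
    g[[paste0(Wn, "_b")]] <<- cb$db
    cb$dX
  }

  if (model$type == "dual") {
    s <- cache$split
    dff <- dfused[, 1:s, drop = FALSE]
    drf <- dfused[, (s + 1):ncol(dfused), drop = FALSE]
    # feature stream
    dim(dff) <- cache$dim_f2
    df1 <- conv_block_bwd(dff, cache$f2, "fc2", "fbn2")
    conv_block_bwd(df1, cache$f1, "fc1", "fbn1")
    # raw stream
    dim(drf) <- cache$dim_r2
    drl <- conv_block_bwd(drf, cache$r2, "rc2", "rbn2")
    lb <- lstm_bwd(drl, p$rlstm_Wx, p$rlstm_Wh, cache$rlstm)
    g$rlstm_Wx <- lb$dWx; g$rlstm_Wh <- lb$dWh; g$rlstm_b <- lb$db
    conv_block_bwd(lb$dX, cache$r1, "rc1", "rbn1")
  } else {
    dr1 <- dfused; dim(dr1) <- cache$dim_r1
    conv_block_bwd(dr1, cache$r1, "rc1", "rbn1")
  }
  g
}

#' Realized layer-shape trace of a model
#'
#' Runs a probe input through the model (inference mode) and returns the
#' declared and realized per-layer shapes, batch dimension excluded.  Used
#' to verify the implementation against the published layer table.
#'
#' @param model a `fusion_model`.
#' @param batch probe batch size (non-batch shapes are batch-invariant).
#' @return data.frame with columns `layer`, `declared`, `realized`, `match`.
#' @export
shape_trace <- function(model, batch = 2L) {
  spec <- model$spec
  Xr <- array(stats::rnorm(batch * spec$nf * spec$window_samples *
                             spec$n_channels),
              dim = c(batch, spec$nf, spec$window_samples, spec$n_channels))
  Xf <- if (model$type == "dual")
    array(stats::rnorm(batch * spec$nf * spec$n_features * spec$n_channels),
          dim = c(batch, spec$nf, spec$n_features, spec$n_channels))
  fw <- model_forward(model, Xf, Xr, training = FALSE)
  realized <- vapply(fw$shapes, function(s) shp(s), character(1))
  df <- model$graph
  names(df)[names(df) == "shape"] <- "declared"
  key <- sub("^input_feature$", "input_feature", df$layer)
  df$realized <- unname(realized[df$layer])
  df$match <- df$declared == df$realized
  df
}

#' One step of the LSTM cell recurrence (reference oracle)
#'
#' Direct transcription of the gated cell update used by the recurrent
#' layers, with distinct input and recurrent weight matrices per gate
#' (candidate, input, forget, output):
#' `g = tanh(W_c x + U_c h + b_c)`, `i/f/o = sigmoid(W x + U h + b)`,
#' `c' = f * c + i * g`, `h' = o * tanh(c')`.  Serves as an independent
#' unit-test oracle for the batched recurrent layer.
#'
#' @param cell list with matrices `W_c, U_c, W_i, U_i, W_f, U_f, W_o, U_o`
#'   (each `H x D` / `H x H`) and bias vectors `b_c, b_i, b_f, b_o`.
#' @param x_t input column vector (length D).
#' @param h_prev,c_prev previous hidden/cell state vectors (length H).
#' @return list with `h` and `c`.
#' @export
lstm_cell_step <- function(cell, x_t, h_prev, c_prev) {
  x_t <- as.numeric(x_t); h_prev <- as.numeric(h_prev)
  c_prev <- as.numeric(c_prev)
  if (ncol(cell$W_c) != length(x_t) || ncol(cell$U_c) != length(h_prev))
    stop("lstm_cell_step: shape mismatch")
  g <- tanh(drop(cell$W_c %*% x_t + cell$U_c %*% h_prev) + cell$b_c)
  i <- sigmoid(drop(cell$W_i %*% x_t + cell$U_i %*% h_prev) + cell$b_i)
  f <- sigmoid(drop(cell$W_f %*% x_t + cell$U_f %*% h_prev) + cell$b_f)
  o <- sigmoid(drop(cell$W_o %*% x_t + cell$U_o %*% h_prev) + cell$b_o)
  c_new <- f * c_prev + i * g
  list(h = o * tanh(c_new), c = c_new)
}

# pack a lstm_cell_step cell into the (D,4H)/(H,4H) layout of lstm_fwd
cell_to_layer <- function(cell) {
  list(Wx = cbind(t(cell$W_i), t(cell$W_f), t(cell$W_c), t(cell$W_o)),
       Wh = cbind(t(cell$U_i), t(cell$U_f), t(cell$U_c), t(cell$U_o)),
       b = c(cell$b_i, cell$b_f, cell$b_c, cell$b_o))
}

#' Desk-scale model preset
#'
#' A reduced-width instance of the same architecture for CPU-scale runs
#' (tests, demos): 16 filters, 16 inner recurrent units, 16 Bi-LSTM units
#' per direction, 64 dense units, light regularization.  The layer
#' structure and all shape arithmetic are identical to the full model;
#' only widths shrink.
#'
#' @param n_classes,n_channels task geometry.
#' @param conv_filters,inner_units,bilstm_units,dense_units widths.
#' @param ... forwarded to [model_spec()].
#' @return a [model_spec()].
#' @export
desk_model_spec <- function(n_classes, n_channels = 10L, conv_filters = 16L,
                            inner_units = 16L, bilstm_units = 16L,
                            dense_units = 64L, ...) {
  model_spec(n_classes = n_classes, n_channels = n_channels,
             conv_filters = conv_filters, inner_units = inner_units,
             bilstm_units = bilstm_units, dense_units = dense_units,
             dropout_conv = 0.1, dropout_dense = 0.2, l2 = 1e-4, ...)
}
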