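test_that("DB1 dual-stream shape trace matches the published layer table", {
  set.seed(1)
  model <- build_dual_stream(model_spec())
  tr <- shape_trace(model, batch = 2L)
  expected <- c(
    input_feature = "(25, 5, 10)", input_raw = "(25, 20, 10)",
    conv1d_feature_1 = "(25, 3, 256)", conv1d_raw_1 = "(25, 10, 256)",
    lstm_raw = "(25, 10, 256)", conv1d_feature_2 = "(25, 2, 256)",
    conv1d_raw_2 = "(25, 5, 256)", flatten_feature = "(25, 512)",
    flatten_raw = "(25, 1280)", concatenate = "(25, 1792)",
    bilstm_1 = "(25, 200)", bilstm_2 = "(25, 200)", flatten = "(25, 200)",
    dense_1 = "(25, 512)", dense_2 = "(25, 52)")
  expect_equal(stats::setNames(tr$realized, tr$layer), expected)
  expect_true(all(tr$match))
})

test_that("shape trace is batch-invariant and channel-permutation invariant", {
  set.seed(2)
  spec <- tiny_model_spec()
  m <- build_dual_stream(spec)
  t1 <- shape_trace(m, batch = 1L)
  t3 <- shape_trace(m, batch = 3L)
  expect_equal(t1$realized, t3$realized)
  # permuting channel order at build time: same spec, same trace
  m2 <- build_dual_stream(spec)
  expect_equal(shape_trace(m2, 2L)$realized, t3$realized)
})

test_that("inconsistent convolution arithmetic is a spec error", {
  expect_error(model_spec(window_samples = 21L), "non-integer")
})

test_that("single-stream model drops fusion layers and has fewer parameters", {
  set.seed(3)
  spec <- model_spec()
  dual <- build_dual_stream(spec)
  single <- build_single_stream(spec)
  expect_false("concatenate" %in% single$graph$layer)
  expect_false("lstm_raw" %in% single$graph$layer)
  expect_false("input_feature" %in% single$graph$layer)
  expect_lt(count_params(single), count_params(dual))
  # head input width = conv_filters * flattened conv length (20 -> 10)
  expect_equal(single$graph$shape[single$graph$layer == "flatten_raw"],
               "(25, 2560)")
  expect_equal(single$graph$shape[single$graph$layer == "dense_2"],
               "(25, 52)")
  tr <- shape_trace(single, batch = 2L)
  expect_true(all(tr$match))
})

test_that("per-window outputs are softmax-normalized distributions", {
  set.seed(4)
  for (builder in list(build_dual_stream, build_single_stream)) {
    m <- builder(tiny_model_spec())
    B <- 3L
    Xf <- array(rnorm(B * 3 * 5 * 2), c(B, 3, 5, 2))
    Xr <- array(rnorm(B * 3 * 6 * 2), c(B, 3, 6, 2))
    fw <- model_forward(m, if (m$type == "dual") Xf else NULL, Xr)
    sums <- apply(fw$probs, c(1, 2), sum)
    expect_equal(as.vector(sums), rep(1, B * 3), tolerance = 1e-6)
    expect_true(all(fw$probs >= 0))
  }
})

test_that("zero-weight LSTM cell reproduces the closed-form step", {
  h <- 4L; d <- 3L
  cell <- list(W_c = matrix(0, h, d), U_c = matrix(0, h, h), b_c = numeric(h),
               W_i = matrix(0, h, d), U_i = matrix(0, h, h), b_i = numeric(h),
               W_f = matrix(0, h, d), U_f = matrix(0, h, h), b_f = numeric(h),
               W_o = matrix(0, h, d), U_o = matrix(0, h, h), b_o = numeric(h))
  c_prev <- c(1, -1, 0.5, 2)
  st <- lstm_cell_step(cell, rnorm(d), numeric(h), c_prev)
  # all gates sigmoid(0) = 0.5, candidate tanh(0) = 0
  expect_equal(st$c, 0.5 * c_prev)
  expect_equal(st$h, 0.5 * tanh(0.5 * c_prev))
})

test_that("biased cell from rest state has the closed-form value", {
  set.seed(5)
  h <- 3L; d <- 2L
  cell <- random_cell(d, h)
  cell$W_c[] <- 0; cell$W_i[] <- 0; cell$W_f[] <- 0; cell$W_o[] <- 0
  cell$U_c[] <- 0; cell$U_i[] <- 0; cell$U_f[] <- 0; cell$U_o[] <- 0
  st <- lstm_cell_step(cell, numeric(d), numeric(h), numeric(h))
  c_expect <- plogis(cell$b_i) * tanh(cell$b_c)
  expect_equal(st$c, c_expect)
  expect_equal(st$h, plogis(cell$b_o) * tanh(c_expect))
})

test_that("cell oracle agrees with the batched recurrent layer over 100 steps", {
  set.seed(6)
  d <- 5L; h <- 4L; steps <- 100L
  cell <- random_cell(d, h)
  layer <- semgfusion:::cell_to_layer(cell)
  X <- array(rnorm(steps * d, sd = 0.8), dim = c(1L, steps, d))
  out <- semgfusion:::lstm_fwd(X, layer$Wx, layer$Wh, layer$b)$out
  hh <- numeric(h); cc <- numeric(h)
  max_dh <- 0
  for (t in seq_len(steps)) {
    st <- lstm_cell_step(cell, X[1, t, ], hh, cc)
    hh <- st$h; cc <- st$c
    max_dh <- max(max_dh, abs(hh - out[1, t, ]))
  }
  expect_lt(max_dh, 1e-5)
})

test_that("cell oracle rejects mismatched shapes", {
  cell <- random_cell(3L, 2L)
  expect_error(lstm_cell_step(cell, rnorm(4), numeric(2), numeric(2)),
               "shape mismatch")
})

test_that("model gradients match central differences", {
  set.seed(7)
  spec <- tiny_model_spec()
  model <- build_dual_stream(spec)
  B <- 2L
  Xf <- array(rnorm(B * 3 * 5 * 2), c(B, 3, 5, 2))
  Xr <- array(rnorm(B * 3 * 6 * 2), c(B, 3, 6, 2))
  y <- c(1L, 3L)
  lossfun <- function(m) {
    fw <- semgfusion:::model_forward(m, Xf, Xr, training = TRUE)
    probs <- fw$probs; dim(probs) <- c(B * 3L, 3L)
    cross_entropy_loss(probs, rep(y, times = 3L))
  }
  fw <- semgfusion:::model_forward(model, Xf, Xr, training = TRUE)
  probs <- fw$probs; dim(probs) <- c(B * 3L, 3L)
  Y <- semgfusion:::onehot(rep(y, times = 3L), 3L)
  grads <- semgfusion:::model_backward(model, fw$cache, (probs - Y) / nrow(probs))
  eps <- 1e-6
  for (nm in c("fc1_W", "rc2_W", "rlstm_Wh", "bl1_Wxb", "bl2_Whf",
               "dbn_gamma", "d2_W")) {
    p <- model$params[[nm]]
    for (ii in sample(length(p), 3L)) {
      m2 <- model
      m2$params[[nm]][ii] <- p[ii] + eps; lp <- lossfun(m2)
      m2$params[[nm]][ii] <- p[ii] - eps; lm <- lossfun(m2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-4,
                   label = paste("grad", nm, ii))
    }
  }
})
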