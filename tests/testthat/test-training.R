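test_that("cross-entropy identities hold", {
  # perfect one-hot prediction -> 0 (up to the probability floor)
  perfect <- diag(4)
  expect_lt(cross_entropy_loss(perfect, 1:4), 1e-10)
  # uniform over 52 classes -> ln 52 per sample
  unif <- matrix(1 / 52, 1, 52)
  expect_equal(cross_entropy_loss(unif, 10L), log(52), tolerance = 1e-12)
  # batch mixing the two -> mean
  batch <- rbind(c(1, rep(0, 51)), rep(1 / 52, 52))
  expect_equal(cross_entropy_loss(batch, c(1L, 5L)), log(52) / 2,
               tolerance = 1e-9)
  expect_error(cross_entropy_loss(matrix(1, 2, 3), matrix(1, 3, 3)),
               "shape mismatch")
  # loss floor
  set.seed(1)
  p <- matrix(runif(40), 8, 5); p <- p / rowSums(p)
  expect_gte(cross_entropy_loss(p, sample(5, 8, TRUE)), 0)
})

test_that("learning-rate schedule drops as configured", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 1e-4)
  expect_equal(lr_schedule(69, cfg), 1e-4)
  expect_equal(lr_schedule(70, cfg), 1e-5)
  expect_equal(lr_schedule(400, cfg), 1e-5)   # single drop by default
  cfg_rep <- train_config(lr_repeat_drops = TRUE)
  expect_equal(lr_schedule(140, cfg_rep), 1e-6)
  cfg_flat <- train_config(lr_drop_factor = 1)
  expect_equal(lr_schedule(300, cfg_flat), 1e-4)
  # monotone non-increasing
  lrs <- vapply(0:200, lr_schedule, numeric(1), config = train_config())
  expect_true(all(diff(lrs) <= 0))
})

test_that("trial aggregation follows the window-mean argmax rule", {
  one_hot7 <- matrix(0, 5, 10); one_hot7[, 7] <- 1
  expect_equal(aggregate_trial(one_hot7), 7L)
  # 13 windows favor class 2, 12 favor class 9 with equal confidence
  wp <- matrix(0.01, 25, 10)
  wp[1:13, 2] <- 0.9; wp[14:25, 9] <- 0.9
  wp <- wp / rowSums(wp)
  expect_equal(aggregate_trial(wp), 2L)
  # exact two-way tie -> lower index
  tie <- rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0))
  expect_equal(aggregate_trial(tie), 1L)
  expect_error(aggregate_trial(matrix(0, 0, 3)), "at least one window")
})

test_that("evaluation report satisfies the confusion-matrix identities", {
  set.seed(10)
  cfg <- tiny_config(n_classes = 3L, n_repetitions = 4L)
  ds <- generate_dataset(cfg, split_rule = list(train = 1:3, val = 4L))
  wspec <- window_spec(200, fs = 100, NT = 100L)
  prep <- prepare_trials(ds$train, wspec)
  spec <- model_spec(nf = wspec$Nf, window_samples = 20L, n_channels = 10L,
                     n_classes = 3L, conv_filters = 4L, inner_units = 4L,
                     bilstm_units = 4L, dense_units = 8L, l2 = 0)
  model <- build_dual_stream(spec)
  rep <- evaluate_model(model, prep)
  expect_equal(sum(rep$confusion), rep$n_trials)
  expect_equal(rep$n_trials, length(ds$train))
  # per-class accuracy = diagonal / row sums; overall = weighted mean
  rs <- rowSums(rep$confusion)
  expect_equal(rep$per_class_accuracy[rs > 0],
               100 * diag(rep$confusion)[rs > 0] / rs[rs > 0])
  expect_equal(rep$accuracy,
               sum(diag(rep$confusion)) / rep$n_trials * 100)
  wt <- stats::weighted.mean(rep$per_class_accuracy[rs > 0], rs[rs > 0])
  expect_equal(rep$accuracy, wt)
})

test_that("training reduces the loss and can overfit a tiny batch", {
  set.seed(11)
  cfg <- tiny_config(n_classes = 2L, n_repetitions = 4L, seed = 31L)
  ds <- generate_dataset(cfg, split_rule = list(train = 1:4, val = integer(0))) |>
    suppressWarnings()
  wspec <- window_spec(200, fs = 100, NT = 100L)
  norm <- fit_normalizer(lapply(ds$train, function(t) t$data))
  prep <- prepare_trials(ds$train, wspec, normalizer = norm)
  spec <- model_spec(nf = wspec$Nf, window_samples = 20L, n_channels = 10L,
                     n_classes = 2L, conv_filters = 6L, inner_units = 6L,
                     bilstm_units = 6L, dense_units = 12L,
                     dropout_conv = 0, dropout_dense = 0, l2 = 0)
  set.seed(12)
  model <- build_dual_stream(spec)
  fit <- train_model(model, prep,
                     config = train_config(epochs = 25L, batch_size = 8L,
                                           base_lr = 3e-3, lr_drop_epoch = 50L,
                                           seed = 12L))
  hist <- fit$history
  expect_lt(hist$loss[10], hist$loss[1])             # descent sanity
  rep <- evaluate_model(fit$model, prep)
  expect_equal(rep$accuracy, 100)                    # capacity sanity
  expect_equal(rep$confusion[1, 2] + rep$confusion[2, 1], 0)
})

test_that("degenerate training inputs raise errors", {
  spec <- tiny_model_spec()
  model <- build_dual_stream(spec)
  empty <- list(Xf = array(0, c(0, 3, 5, 2)), Xr = array(0, c(0, 3, 6, 2)),
                y = integer(0))
  expect_error(train_model(model, empty), "empty training set")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(lr_drop_factor = 0), "lr_drop_factor")
})

test_that("prediction is deterministic at inference and correctly shaped", {
  set.seed(13)
  model <- build_dual_stream(model_spec(conv_filters = 8L, inner_units = 8L,
                                        bilstm_units = 8L, dense_units = 16L))
  prep <- list(Xf = array(rnorm(1 * 25 * 5 * 10), c(1, 25, 5, 10)),
               Xr = array(rnorm(1 * 25 * 20 * 10), c(1, 25, 20, 10)),
               y = 1L)
  p1 <- predict_trial(model, prep)
  p2 <- predict_trial(model, prep)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(25L, 52L))
  expect_equal(rowSums(p1), rep(1, 25), tolerance = 1e-6)
})

test_that("subject-wise runs give per-subject reports and their mean", {
  set.seed(14)
  cfg <- tiny_config(n_classes = 2L, n_repetitions = 5L, seed = 41L)
  ds <- generate_dataset(cfg, n_subjects = 2L,
                         split_rule = list(train = 1:4, val = 5L))
  wspec <- window_spec(200, fs = 100, NT = 100L)
  spec <- model_spec(nf = wspec$Nf, window_samples = 20L, n_channels = 10L,
                     n_classes = 2L, conv_filters = 4L, inner_units = 4L,
                     bilstm_units = 4L, dense_units = 8L,
                     dropout_conv = 0, dropout_dense = 0, l2 = 0)
  res <- run_subject_wise(ds, spec,
                          train_config(epochs = 6L, batch_size = 8L,
                                       base_lr = 3e-3, seed = 7L),
                          wspec = wspec)
  expect_length(res$reports, 2L)
  expect_equal(res$mean_accuracy, mean(res$per_subject_accuracy))
  # subject with no validation trials is excluded with a warning
  ds2 <- ds
  ds2$val <- Filter(function(t) t$subject != 2L, ds2$val)
  expect_warning(res2 <- run_subject_wise(ds2, spec,
                   train_config(epochs = 1L, batch_size = 8L, seed = 7L),
                   wspec = wspec),
                 "no validation trials")
  expect_length(res2$reports, 1L)
})
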