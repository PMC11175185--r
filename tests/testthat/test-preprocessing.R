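make_rec <- function(emg, fs = 100) {
  n <- nrow(emg)
  emg_recording(emg, stimulus = integer(n), repetition = integer(n), fs = fs)
}

test_that("high-pass filter removes DC and passes the band", {
  n <- 2000
  zeroes <- make_rec(matrix(0, n, 2))
  expect_equal(highpass_filter(zeroes)$emg, matrix(0, n, 2))

  dc <- make_rec(matrix(7.5, n, 1))
  out <- highpass_filter(dc)
  expect_lt(max(abs(out$emg)), 7.5 * 1e-6)

  # unit sinusoid at 10x cutoff: designed-response gain is the oracle
  filt <- butter_highpass(1, 100, 2)
  gain <- Mod(filter_response(filt, 10))^2  # zero-phase = squared response
  x <- sin(2 * pi * 10 * (0:(n - 1)) / 100)
  y <- highpass_filter(make_rec(matrix(x, ncol = 1)), cutoff = 1)$emg[, 1]
  mid <- 500:1500
  expect_equal(max(abs(y[mid])), gain * 1, tolerance = 0.05)
  expect_gt(gain, 0.999)  # and the response itself is essentially unity
})

test_that("cutoff at or above Nyquist is rejected", {
  rec <- make_rec(matrix(rnorm(100), 50, 2))
  expect_error(highpass_filter(rec, cutoff = 50), "fs/2")
  expect_error(butter_highpass(60, 100), "fs/2")
})

test_that("filtering a DC-free signal twice is near-idempotent", {
  set.seed(2)
  x <- matrix(rnorm(3000), ncol = 1)
  once <- highpass_filter(make_rec(x))
  twice <- highpass_filter(once)
  # relative change concentrated at the (already attenuated) low band
  expect_lt(sqrt(mean((twice$emg - once$emg)^2)) / sqrt(mean(once$emg^2)),
            0.05)
})

test_that("normalizer matches direct arithmetic and rejects degeneracy", {
  stats <- fit_normalizer(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(stats$mu, 2, ignore_attr = TRUE)
  expect_equal(stats$delta, sqrt(2 / 3), ignore_attr = TRUE)

  set.seed(4)
  big <- matrix(rnorm(1e5), ncol = 1)
  st2 <- fit_normalizer(big)
  expect_equal(st2$mu, 0, tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(st2$delta, 1, tolerance = 0.02, ignore_attr = TRUE)

  expect_error(fit_normalizer(matrix(5, 10, 1)), "degenerate")
  expect_error(fit_normalizer(matrix(1, 1, 2)), ">= 2 samples")
})

test_that("zscore transforms, inverts, and checks channels", {
  x <- matrix(c(1, 2, 3), ncol = 1)
  st <- fit_normalizer(x)
  z <- zscore(x, st)
  expect_equal(as.vector(z), c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  # invertibility
  expect_equal(sweep(sweep(z, 2, st$delta, "*"), 2, st$mu, "+"), x,
               tolerance = 1e-9)
  # identity stats
  st_id <- structure(list(mu = 0, delta = 1, n_channels = 1),
                     class = "normalizer_stats")
  expect_equal(zscore(x, st_id), x)
  expect_error(zscore(matrix(0, 3, 2), st), "channel mismatch")
})

test_that("trial extraction truncates, pads and flags correctly", {
  set.seed(6)
  emg <- matrix(rnorm(2000 * 2), 2000, 2)
  stim <- integer(2000)
  stim[101:600] <- 1L   # exactly 500
  stim[701:1300] <- 2L  # 600: truncated
  stim[1401:1880] <- 3L # 480: padded
  rep_v <- integer(2000); rep_v[stim != 0] <- 1L
  rec <- emg_recording(emg, stim, rep_v, fs = 100)
  trials <- extract_trials(rec, trial_spec(5, 100))
  expect_length(trials, 3L)
  expect_equal(vapply(trials, function(t) nrow(t$data), 1L), rep(500L, 3))
  expect_false(trials[[1]]$padded)
  expect_equal(trials[[1]]$data, emg[101:600, ])
  expect_false(trials[[2]]$padded)
  expect_equal(trials[[2]]$data, emg[701:1200, ])  # first NT samples
  expect_true(trials[[3]]$padded)
  expect_equal(trials[[3]]$data[481:500, ], matrix(0, 20, 2))
  expect_equal(vapply(trials, `[[`, 1L, "label"), 1:3)
})

test_that("a label-free recording yields an empty list with a warning", {
  rec <- make_rec(matrix(rnorm(100), 50, 2))
  expect_warning(trials <- extract_trials(rec), "no nonzero labels")
  expect_length(trials, 0L)
})

test_that("window counts follow floor((NT - W)/S) + 1", {
  ws <- window_spec(200, fs = 100, NT = 500L)
  expect_equal(ws$window_samples, 20L)
  expect_equal(ws$Nf, 25L)
  expect_equal(window_spec(50, fs = 100, NT = 500L)$Nf, 100L)
  expect_error(window_spec(6000, fs = 100, NT = 500L), "longer than trial")

  trial <- structure(list(data = matrix(rnorm(500 * 3), 500, 3), label = 1L,
                          repetition = 1L, subject = 1L, padded = FALSE),
                     class = "emg_trial")
  rw <- slide_windows(trial, ws)
  expect_equal(dim(rw$data), c(25L, 20L, 3L))
  # overlapping stride
  ws2 <- window_spec(200, 50, fs = 100, NT = 500L)
  expect_equal(ws2$Nf, 97L)
})

test_that("non-overlapping windows reconstruct the trial exactly", {
  set.seed(8)
  trial <- structure(list(data = matrix(rnorm(500 * 2), 500, 2), label = 1L,
                          repetition = 1L, subject = 1L, padded = FALSE),
                     class = "emg_trial")
  ws <- window_spec(200, fs = 100, NT = 500L)
  rw <- slide_windows(trial, ws)
  recon <- do.call(rbind, lapply(1:25, function(k) rw$data[k, , ]))
  expect_equal(recon, trial$data)
})

test_that("trial/window spec invariants are validated", {
  expect_error(trial_spec(0.333, 3), "integer")
  expect_equal(trial_spec(5, 100)$NT, 500L)
  spec <- window_spec(200, fs = 100, NT = 500L)
  trial <- structure(list(data = matrix(0, 100, 1), label = 1L,
                          repetition = 1L, subject = 1L, padded = FALSE),
                     class = "emg_trial")
  expect_error(slide_windows(trial, window_spec(200, fs = 100, NT = 100L)),
               NA)  # 100-sample trial, 20-sample window: fine
  long_w <- window_spec(600, fs = 100, NT = 60L)   # 60-sample window
  short_trial <- structure(list(data = matrix(0, 50, 1), label = 1L,
                                repetition = 1L, subject = 1L, padded = FALSE),
                           class = "emg_trial")
  expect_error(slide_windows(short_trial, long_w), "longer than trial")
})
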