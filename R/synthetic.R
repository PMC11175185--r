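#' Configuration for the synthetic sEMG generator
#'
#' Describes a DB1-like acquisition: 10 electrodes at 100 Hz, 5-s gesture
#' activations separated by 3-s rests, repeated `n_repetitions` times per
#' gesture.  Each activation is band-limited Gaussian noise (the classic
#' amplitude-modulated Gaussian model of surface EMG) scaled per channel by
#' a class-specific envelope, with a trapezoidal onset/offset ramp and
#' baseline noise everywhere.
#'
#' @param n_classes number of gesture classes (>= 2).
#' @param n_repetitions repetitions per class.
#' @param n_channels electrode count (default 10).
#' @param fs sampling rate in Hz (default 100).
#' @param active_duration gesture duration in seconds (default 5).
#' @param rest_duration rest between gestures in seconds (default 3).
#' @param envelope_amplitudes `n_classes x n_channels` matrix of non-negative
#'   per-channel gains; defaults to [default_envelopes()] (>= 2x separated).
#' @param carrier_band `(low, high)` band in Hz of the Gaussian carrier,
#'   inside `(0, fs/2)`; default `c(5, 45)`.
#' @param noise_sd baseline noise standard deviation (default 0.05).
#' @param ramp_duration trapezoidal onset/offset ramp in seconds (default
#'   0.2) to avoid step artifacts at activation edges.
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes, n_repetitions,
                             n_channels = 10L, fs = 100,
                             active_duration = 5, rest_duration = 3,
                             envelope_amplitudes = NULL,
                             carrier_band = c(5, 45),
                             noise_sd = 0.05, ramp_duration = 0.2,
                             seed = 1L) {
  if (n_channels < 1L) stop("synthetic_config: n_channels must be >= 1")
  if (n_classes < 2L) stop("synthetic_config: n_classes must be >= 2")
  if (n_repetitions < 1L) stop("synthetic_config: n_repetitions must be >= 1")
  if (active_duration <= 0 || rest_duration <= 0 || fs <= 0)
    stop("synthetic_config: durations and fs must be > 0")
  if (is.null(envelope_amplitudes))
    envelope_amplitudes <- default_envelopes(n_classes, n_channels)
  envelope_amplitudes <- as.matrix(envelope_amplitudes)
  if (!all(dim(envelope_amplitudes) == c(n_classes, n_channels)))
    stop("synthetic_config: envelope_amplitudes must be n_classes x n_channels")
  if (any(envelope_amplitudes < 0))
    stop("synthetic_config: envelope amplitudes must be >= 0")
  if (length(carrier_band) != 2L || carrier_band[1] <= 0 ||
      carrier_band[2] <= carrier_band[1] || carrier_band[2] >= fs / 2)
    stop("synthetic_config: carrier_band must be 0 < low < high < fs/2")
  if (noise_sd < 0) stop("synthetic_config: noise_sd must be >= 0")
  structure(
    list(n_channels = as.integer(n_channels), fs = fs,
         n_classes = as.integer(n_classes),
         n_repetitions = as.integer(n_repetitions),
         active_duration = active_duration, rest_duration = rest_duration,
         envelope_amplitudes = envelope_amplitudes,
         carrier_band = carrier_band, noise_sd = noise_sd,
         ramp_duration = ramp_duration, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Default class-conditional envelope matrix
#'
#' Class `k` gets an overall gain `separation^(k-1)` (so consecutive classes
#' are separated by at least a factor `separation` in amplitude) modulated
#' by a class-specific spatial profile: a smooth bump over the electrode
#' array whose center rotates with the class, emulating different muscles
#' dominating different gestures.
#'
#' @param n_classes,n_channels matrix dimensions.
#' @param separation amplitude ratio between consecutive classes (default 2).
#' @return `n_classes x n_channels` gain matrix.
#' @export
default_envelopes <- function(n_classes, n_channels, separation = 2) {
  amp <- matrix(0, n_classes, n_channels)
  for (k in seq_len(n_classes)) {
    center <- 1 + (k - 1) * max(1, n_channels %/% n_classes)
    d <- pmin(abs(seq_len(n_channels) - center),
              n_channels - abs(seq_len(n_channels) - center))  # circular
    profile <- 0.4 + exp(-d^2 / 8)
    amp[k, ] <- separation^(k - 1) * profile
  }
  amp
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# band-limited unit-variance Gaussian noise via FFT masking
bandlimited_noise <- function(n, n_channels, band, fs) {
  x <- matrix(stats::rnorm(n * n_channels), n, n_channels)
  freq <- (seq_len(n) - 1L) * fs / n
  freq <- pmin(freq, fs - freq)              # two-sided spectrum
  mask <- freq >= band[1] & freq <= band[2]
  xf <- stats::mvfft(x)
  xf[!mask, ] <- 0
  y <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  sweep(y, 2L, pmax(apply(y, 2L, stats::sd), .Machine$double.eps), "/")
}

#' Generate one DB1-like synthetic recording
#'
#' Produces a continuous recording in which every class contributes exactly
#' `n_repetitions` activations of `active_duration * fs` samples, separated
#' by rests; the stimulus stream is 0 during rest and the 1-based class
#' index during activations, and the repetition stream carries the 1-based
#' repetition index.  Activations are laid out class-major (all repetitions
#' of class 1, then class 2, ...), as in guided acquisition protocols.
#'
#' @param config a [synthetic_config()].
#' @param subject_id subject identifier; perturbs the random stream
#'   deterministically so subjects differ but are reproducible.
#' @return an [emg_recording()].
#' @export
generate_recording <- function(config, subject_id = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$fs
  n_act <- as.integer(round(config$active_duration * fs))
  n_rest <- as.integer(round(config$rest_duration * fs))
  nc <- config$n_channels
  n_trials <- config$n_classes * config$n_repetitions
  total <- n_rest + n_trials * (n_act + n_rest)
  ramp_n <- min(as.integer(round(config$ramp_duration * fs)), n_act %/% 2L)
  ramp <- if (ramp_n > 0L) {
    up <- seq_len(ramp_n) / ramp_n
    c(up, rep(1, n_act - 2L * ramp_n), rev(up))
  } else rep(1, n_act)

  with_rng(config$seed + 7919L * as.integer(subject_id), {
    emg <- matrix(stats::rnorm(total * nc, sd = config$noise_sd), total, nc)
    stimulus <- integer(total)
    repetition <- integer(total)
    pos <- n_rest
    for (cls in seq_len(config$n_classes)) {
      for (rep_i in seq_len(config$n_repetitions)) {
        idx <- (pos + 1L):(pos + n_act)
        carrier <- bandlimited_noise(n_act, nc, config$carrier_band, fs)
        gain <- config$envelope_amplitudes[cls, ]
        emg[idx, ] <- emg[idx, ] +
          (carrier * ramp) %*% diag(gain, nrow = nc)
        stimulus[idx] <- cls
        repetition[idx] <- rep_i
        pos <- pos + n_act + n_rest
      }
    }
    emg_recording(emg, stimulus, repetition, fs, subject = subject_id)
  })
}

#' Generate a subject-wise synthetic dataset with a repetition split
#'
#' Generates one recording per subject, extracts fixed-length trials, and
#' routes each trial to the training or validation set strictly by its
#' repetition index.  The two repetition sets must be disjoint.
#'
#' @param config a [synthetic_config()].
#' @param n_subjects number of subjects to simulate.
#' @param split_rule list with integer vectors `train` and `val` of
#'   repetition indices, e.g. `list(train = 1:7, val = 8:10)`.
#' @param highpass_cutoff if non-`NULL`, each recording is zero-phase
#'   Butterworth high-pass filtered at this cutoff (Hz) before trial
#'   extraction, as in the real-data pipeline.
#' @param highpass_order Butterworth order for the optional filter.
#' @return list with `train` and `val` (lists of `emg_trial`), each trial
#'   carrying its subject id.
#' @export
generate_dataset <- function(config, n_subjects = 1L,
                             split_rule = list(train = 1:7, val = 8:10),
                             highpass_cutoff = NULL, highpass_order = 2L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(intersect(split_rule$train, split_rule$val)))
    stop("generate_dataset: train/val repetition sets overlap")
  if (!length(split_rule$val))
    warning("generate_dataset: empty validation repetition set")
  tspec <- trial_spec(config$active_duration, config$fs)
  train <- list(); val <- list()
  for (s in seq_len(n_subjects)) {
    rec <- generate_recording(config, subject_id = s)
    if (!is.null(highpass_cutoff))
      rec <- highpass_filter(rec, highpass_cutoff, highpass_order)
    trials <- extract_trials(rec, tspec)
    for (tr in trials) {
      if (tr$repetition %in% split_rule$train) train[[length(train) + 1L]] <- tr
      else if (tr$repetition %in% split_rule$val) val[[length(val) + 1L]] <- tr
    }
  }
  list(train = train, val = val)
}
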