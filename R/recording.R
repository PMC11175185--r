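#' Multi-channel sEMG recording container
#'
#' Holds a continuous recording: `emg` (samples x channels), a per-sample
#' gesture label stream `stimulus` (0 = rest, 1..K = gesture class), a
#' per-sample `repetition` index, the sampling rate `fs` and a subject id.
#' This mirrors the layout of NinaPro subject files so the same trial
#' extractor serves real and synthetic data.
#'
#' @param emg numeric matrix, samples x channels.
#' @param stimulus integer vector, one label per sample (0 = rest).
#' @param repetition integer vector, one repetition index per sample.
#' @param fs sampling rate in Hz.
#' @param subject subject identifier.
#' @return object of class `emg_recording`.
#' @export
emg_recording <- function(emg, stimulus, repetition, fs, subject = 1L) {
  emg <- as.matrix(emg)
  if (!is.numeric(emg)) stop("emg_recording: emg must be numeric")
  n <- nrow(emg)
  if (length(stimulus) != n)
    stop("emg_recording: stimulus length (", length(stimulus),
         ") != emg rows (", n, ")")
  if (length(repetition) != n)
    stop("emg_recording: repetition length (", length(repetition),
         ") != emg rows (", n, ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("emg_recording: fs must be a positive scalar")
  if (ncol(emg) < 1L) stop("emg_recording: need at least one channel")
  structure(
    list(emg = emg, stimulus = as.integer(stimulus),
         repetition = as.integer(repetition), fs = fs,
         subject = subject),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> subject %s: %d samples x %d channels @ %g Hz, %d active segments\n",
    format(x$subject), nrow(x$emg), ncol(x$emg), x$fs,
    n_label_runs(x$stimulus)))
  invisible(x)
}

# number of contiguous nonzero-label runs in a stimulus stream
n_label_runs <- function(stimulus) {
  active <- stimulus != 0L
  sum(active & !c(FALSE, active[-length(active)]))
}

#' Trial geometry
#'
#' `NT = Ns * T` samples per trial: `T` seconds at `Ns` Hz.  For DB1-style
#' recordings (5-s activations at 100 Hz), `NT = 500`.
#'
#' @param T_sec trial duration in seconds.
#' @param fs sampling rate (Hz).
#' @return object of class `trial_spec` with fields `NT`, `T_sec`, `fs`.
#' @export
trial_spec <- function(T_sec = 5, fs = 100) {
  if (T_sec <= 0 || fs <= 0) stop("trial_spec: durations and rates must be > 0")
  nt <- fs * T_sec
  if (abs(nt - round(nt)) > 1e-9)
    stop("trial_spec: NT = fs * T must be an integer, got ", nt)
  structure(list(NT = as.integer(round(nt)), T_sec = T_sec, fs = fs),
            class = "trial_spec")
}

#' Sliding-window geometry
#'
#' Windows of `window_ms` milliseconds advanced by `stride_ms`; the number
#' of windows per trial is `Nf = floor((NT - W)/S) + 1`.  The default stride
#' equals the window length (non-overlapping), which is the only stride
#' giving `Nf = 25` for 200-ms windows over a 500-sample trial.
#'
#' @param window_ms window length (ms).
#' @param stride_ms stride between window starts (ms); defaults to
#'   `window_ms` (non-overlapping).
#' @param fs sampling rate (Hz).
#' @param NT samples per trial.
#' @return object of class `window_spec` with `window_samples`,
#'   `stride_samples` and `Nf`.
#' @export
window_spec <- function(window_ms = 200, stride_ms = window_ms,
                        fs = 100, NT = 500L) {
  if (window_ms <= 0 || stride_ms <= 0) stop("window_spec: sizes must be > 0")
  w <- as.integer(round(window_ms * fs / 1000))
  s <- as.integer(round(stride_ms * fs / 1000))
  if (w < 1L || s < 1L)
    stop("window_spec: window/stride shorter than one sample at fs = ", fs)
  if (w > NT)
    stop("window_spec: window (", w, " samples) longer than trial (", NT, ")")
  nf <- (NT - w) %/% s + 1L
  structure(list(window_ms = window_ms, stride_ms = stride_ms,
                 window_samples = w, stride_samples = s,
                 Nf = as.integer(nf), NT = as.integer(NT), fs = fs),
            class = "window_spec")
}
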