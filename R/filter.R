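# IIR high-pass filtering for sEMG preprocessing.
#
# Butterworth design is done in zero-pole-gain form (analog low-pass
# prototype -> high-pass transform -> bilinear transform), which is
# numerically stable for the low orders used here.  No external DSP
# package is required.

# polynomial coefficients (descending powers) from roots, by convolution
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rk in r) p <- c(p, 0) - c(0, p * rk)
  p
}

#' Design a digital Butterworth high-pass filter
#'
#' Analog prototype poles are pre-warped and mapped through the bilinear
#' transform; the result is returned as transfer-function coefficients
#' `b` (numerator) and `a` (denominator), `a[1] = 1`.
#'
#' @param cutoff cutoff frequency in Hz; must satisfy `0 < cutoff < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order filter order (>= 1); default 2.
#' @return list with `b`, `a`, `order`, `cutoff`, `fs`.
#' @export
butter_highpass <- function(cutoff, fs, order = 2L) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("butter_highpass: cutoff must lie in (0, fs/2) = (0, ", fs / 2,
         "), got ", cutoff)
  if (order < 1L) stop("butter_highpass: order must be >= 1")
  n <- as.integer(order)
  # analog low-pass prototype: poles on the unit circle, left half-plane
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  warped <- 2 * fs * tan(pi * cutoff / fs)
  # low-pass -> high-pass: p -> wo/p, n zeros at the origin
  p_hp <- warped / p_lp
  z_hp <- rep(0 + 0i, n)
  k_hp <- Re(1 / prod(-p_lp))
  # bilinear transform at 2*fs
  fs2 <- 2 * fs
  p_d <- (fs2 + p_hp) / (fs2 - p_hp)
  z_d <- (fs2 + z_hp) / (fs2 - z_hp)
  k_d <- k_hp * Re(prod(fs2 - z_hp) / prod(fs2 - p_hp))
  b <- Re(poly_from_roots(z_d)) * k_d
  a <- Re(poly_from_roots(p_d))
  list(b = b / a[1], a = a / a[1], order = n, cutoff = cutoff, fs = fs)
}

#' Frequency response of a digital filter
#'
#' @param filt list with `b`, `a` as from [butter_highpass()].
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate (Hz).
#' @return complex response values `H(e^{i 2 pi f / fs})`.
#' @export
filter_response <- function(filt, f, fs = filt$fs) {
  w <- 2 * pi * f / fs
  ew <- exp(-1i * outer(w, seq_along(filt$b) - 1))
  num <- drop(ew %*% filt$b)
  ew <- exp(-1i * outer(w, seq_along(filt$a) - 1))
  den <- drop(ew %*% filt$a)
  num / den
}

# zero-state IIR difference equation, via the C-level stats::filter
lfilter0 <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  v
}

# zero-phase forward-backward filtering with odd-symmetric edge padding.
# Pad length is chosen so the zero-state transient decays below 1e-10
# before it reaches the data.
filtfilt0 <- function(b, a, x) {
  nx <- length(x)
  r <- max(Mod(polyroot(rev(a))))
  padlen <- if (r < 1 && r > 0) ceiling(log(1e-10) / log(r)) else 3 * length(a)
  padlen <- max(padlen, 3 * (max(length(a), length(b)) - 1))
  padlen <- min(padlen, nx - 1L)
  front <- 2 * x[1L] - x[(padlen + 1L):2L]
  back  <- 2 * x[nx] - x[(nx - 1L):(nx - padlen)]
  y <- lfilter0(b, a, c(front, x, back))
  y <- rev(lfilter0(b, a, rev(y)))
  y[(padlen + 1L):(padlen + nx)]
}

#' Zero-phase Butterworth high-pass filter a recording
#'
#' Applies a forward-backward (zero-phase) Butterworth high-pass filter to
#' every channel of a recording.  Label streams are untouched.  Zero-phase
#' application keeps features aligned with the per-sample labels; the
#' effective magnitude response is the squared single-pass response.
#'
#' @param recording an [emg_recording()].
#' @param cutoff high-pass cutoff in Hz (default 1: removes offset/motion
#'   drift while leaving the informative 20-200 Hz band intact as far as
#'   the sampling rate allows).
#' @param order Butterworth order (default 2).
#' @return a filtered copy of the recording.
#' @export
highpass_filter <- function(recording, cutoff = 1, order = 2L) {
  stopifnot(inherits(recording, "emg_recording"))
  filt <- butter_highpass(cutoff, recording$fs, order)
  out <- recording
  for (ch in seq_len(ncol(recording$emg)))
    out$emg[, ch] <- filtfilt0(filt$b, filt$a, recording$emg[, ch])
  out
}

#' Fit per-channel Z-score statistics
#'
#' Computes the per-channel mean and population standard deviation over all
#' rows of the supplied matrices (typically the training portion only, so no
#' information leaks from validation data).
#'
#' @param train_data a numeric matrix or a list of matrices with equal
#'   channel counts.
#' @return object of class `normalizer_stats` with `mu` and `delta`.
#' @export
fit_normalizer <- function(train_data) {
  if (is.matrix(train_data)) train_data <- list(train_data)
  x <- do.call(rbind, train_data)
  if (nrow(x) < 2L) stop("fit_normalizer: need >= 2 samples per channel")
  mu <- colMeans(x)
  delta <- sqrt(colMeans(sweep(x, 2L, mu)^2))  # population sd
  bad <- which(delta == 0)
  if (length(bad))
    stop("fit_normalizer: degenerate (constant) channel(s): ",
         paste(bad, collapse = ", "))
  structure(list(mu = mu, delta = delta, n_channels = ncol(x)),
            class = "normalizer_stats")
}

#' Apply Z-score normalization
#'
#' Transforms every sample to `(x - mu) / delta` channel-wise.
#'
#' @param recording an [emg_recording()] (or a plain matrix).
#' @param stats a [fit_normalizer()] result.
#' @return normalized copy of the input.
#' @export
zscore <- function(recording, stats) {
  stopifnot(inherits(stats, "normalizer_stats"))
  if (is.matrix(recording)) {
    if (ncol(recording) != stats$n_channels)
      stop("zscore: channel mismatch (", ncol(recording), " vs ",
           stats$n_channels, ")")
    return(sweep(sweep(recording, 2L, stats$mu), 2L, stats$delta, "/"))
  }
  stopifnot(inherits(recording, "emg_recording"))
  if (ncol(recording$emg) != stats$n_channels)
    stop("zscore: channel mismatch (", ncol(recording$emg), " vs ",
         stats$n_channels, ")")
  out <- recording
  out$emg <- sweep(sweep(recording$emg, 2L, stats$mu), 2L, stats$delta, "/")
  out
}
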