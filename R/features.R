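#' Time-domain sEMG features
#'
#' The five classic Hudgins-set time-domain descriptors of a windowed sEMG
#' channel: mean absolute value (MAV), zero crossings (ZC), slope sign
#' changes (SSC), waveform length (WL) and root mean square (RMS).  Each
#' operates on one window of one channel, a numeric vector `x`.
#'
#' Definitions (window `x[1..k]`):
#' \itemize{
#'   \item `emg_mav(x)  = mean(|x|)`
#'   \item `emg_rms(x)  = sqrt(mean(x^2))`
#'   \item `emg_wl(x)   = sum(|x[n+1] - x[n]|)`
#'   \item `emg_zc(x, t)`: number of adjacent pairs with `x[i]*x[i+1] < 0`
#'         and `|x[i] - x[i+1]| >= t`
#'   \item `emg_ssc(x, t)`: number of interior points where
#'         `(x[i]-x[i-1]) * (x[i]-x[i+1]) >= t`; with `t = 0`, zero
#'         products (flat neighborhoods) are not counted, so a constant
#'         window has no slope sign changes
#' }
#'
#' MAV, RMS and WL are absolutely homogeneous (`f(a*x) = |a| f(x)`); ZC and
#' SSC with zero threshold are scale-invariant for nonzero scalings, and all
#' five are invariant under sign flip of the window.
#'
#' @param x numeric vector, one window of one channel.
#' @param threshold non-negative amplitude threshold for ZC/SSC (default 0,
#'   the common baseline on Z-scored data).
#' @return a single numeric value (a count for ZC/SSC).
#' @name td_features
NULL

#' @rdname td_features
#' @export
emg_mav <- function(x) {
  if (length(x) < 1L) stop("mav: window must contain at least 1 sample")
  mean(abs(x))
}

#' @rdname td_features
#' @export
emg_rms <- function(x) {
  if (length(x) < 1L) stop("rms: window must contain at least 1 sample")
  sqrt(mean(x^2))
}

#' @rdname td_features
#' @export
emg_wl <- function(x) {
  if (length(x) < 2L) stop("wl: window must contain at least 2 samples")
  sum(abs(diff(x)))
}

#' @rdname td_features
#' @export
emg_zc <- function(x, threshold = 0) {
  if (length(x) < 2L) stop("zc: window must contain at least 2 samples")
  if (threshold < 0) stop("zc: threshold must be >= 0")
  a <- x[-length(x)]
  b <- x[-1L]
  sum(a * b < 0 & abs(a - b) >= threshold)
}

#' @rdname td_features
#' @export
emg_ssc <- function(x, threshold = 0) {
  k <- length(x)
  if (k < 3L) stop("ssc: window must contain at least 3 samples")
  if (threshold < 0) stop("ssc: threshold must be >= 0")
  mid  <- x[2:(k - 1L)]
  left <- x[1:(k - 2L)]
  right <- x[3:k]
  v <- (mid - left) * (mid - right)
  # at threshold 0, a zero product (flat neighborhood) is not a slope change
  if (threshold > 0) sum(v >= threshold) else sum(v > 0)
}

#' Feature-extraction configuration
#'
#' Fixes the ZC/SSC thresholds and the feature ordering of the per-window
#' feature vector.  The order is fixed to (MAV, ZC, SSC, WL, RMS) so that
#' persisted tensors are interoperable.
#'
#' @param zc_threshold,ssc_threshold non-negative amplitude thresholds.
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(zc_threshold = 0, ssc_threshold = 0) {
  if (zc_threshold < 0 || ssc_threshold < 0)
    stop("feature_config: thresholds must be >= 0")
  structure(
    list(zc_threshold = zc_threshold,
         ssc_threshold = ssc_threshold,
         feature_order = c("MAV", "ZC", "SSC", "WL", "RMS")),
    class = "feature_config")
}

#' Compute the per-trial feature tensor from raw windows
#'
#' For each of the `Nf` windows and `C` channels, computes the five
#' time-domain features, producing an `Nf x 5 x C` array whose middle
#' dimension follows `config$feature_order`.  For the DB1 geometry
#' (25 windows, 10 channels) the result is 25 x 5 x 10.
#'
#' @param windows an object of class `raw_windows` (see [slide_windows()]).
#' @param config a [feature_config()].
#' @return an object of class `feature_tensor`: list with `data`
#'   (`Nf x 5 x C` array), `label`, `subject`, `repetition`, `config`.
#' @export
build_feature_tensor <- function(windows, config = feature_config()) {
  stopifnot(inherits(windows, "raw_windows"))
  d <- windows$data
  nf <- dim(d)[1L]; w <- dim(d)[2L]; nc <- dim(d)[3L]
  if (w < 3L) stop("build_feature_tensor: windows of length ", w,
                   " are too short for SSC (need >= 3 samples)")
  out <- array(0, dim = c(nf, 5L, nc),
               dimnames = list(NULL, config$feature_order, NULL))
  # vectorized over windows x channels: operate on the W axis of the cube
  absd <- abs(d)
  out[, 1L, ] <- apply(absd, c(1L, 3L), mean)                        # MAV
  sq <- d * d
  out[, 5L, ] <- sqrt(apply(sq, c(1L, 3L), mean))                    # RMS
  dif <- d[, -1L, , drop = FALSE] - d[, -w, , drop = FALSE]
  out[, 4L, ] <- apply(abs(dif), c(1L, 3L), sum)                     # WL
  a <- d[, -w, , drop = FALSE]; b <- d[, -1L, , drop = FALSE]
  zc_hit <- (a * b < 0) & (abs(a - b) >= config$zc_threshold)
  out[, 2L, ] <- apply(zc_hit, c(1L, 3L), sum)                       # ZC
  mid <- d[, 2:(w - 1L), , drop = FALSE]
  lft <- d[, 1:(w - 2L), , drop = FALSE]
  rgt <- d[, 3:w, , drop = FALSE]
  v <- (mid - lft) * (mid - rgt)
  ssc_hit <- if (config$ssc_threshold > 0) v >= config$ssc_threshold else v > 0
  out[, 3L, ] <- apply(ssc_hit, c(1L, 3L), sum)                      # SSC
  structure(
    list(data = out, label = windows$label, subject = windows$subject,
         repetition = windows$repetition, config = config),
    class = "feature_tensor")
}

#' Export a feature tensor in long format
#'
#' @param ft a `feature_tensor`.
#' @param trial optional trial identifier column value.
#' @return data.frame with columns trial, window, channel, feature, value.
#' @export
feature_tensor_long <- function(ft, trial = NA_integer_) {
  stopifnot(inherits(ft, "feature_tensor"))
  d <- ft$data
  nf <- dim(d)[1L]; nc <- dim(d)[3L]
  data.frame(
    trial = trial,
    window = rep(seq_len(nf), times = 5L * nc),
    feature = rep(rep(ft$config$feature_order, each = nf), times = nc),
    channel = rep(seq_len(nc), each = nf * 5L),
    value = as.vector(d),
    stringsAsFactors = FALSE)
}
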