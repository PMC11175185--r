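#' Cut a recording into fixed-length labeled trials
#'
#' Each contiguous nonzero run of the stimulus stream becomes one trial.
#' Runs longer than `spec$NT` are truncated to their first `NT` samples;
#' shorter runs are zero-padded at the end and flagged (`padded = TRUE`) so
#' trial counts still match the dataset bookkeeping `N = S * Na * R`.
#' Rest samples (label 0) are discarded.
#'
#' @param recording an [emg_recording()].
#' @param spec a [trial_spec()]; default NT = 500 (5 s at 100 Hz).
#' @return list of `emg_trial` objects, each with `data` (`NT x C` matrix),
#'   `label`, `repetition`, `subject`, `padded`.
#' @export
extract_trials <- function(recording, spec = trial_spec()) {
  stopifnot(inherits(recording, "emg_recording"),
            inherits(spec, "trial_spec"))
  stim <- recording$stimulus
  n <- length(stim)
  if (all(stim == 0L)) {
    warning("extract_trials: no nonzero labels; returning empty list")
    return(list())
  }
  # run-length boundaries of the label stream
  r <- rle(stim)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  nt <- spec$NT
  nc <- ncol(recording$emg)
  trials <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    s <- starts[i]; e <- ends[i]
    len <- e - s + 1L
    padded <- len < nt
    take <- min(len, nt)
    dat <- recording$emg[s:(s + take - 1L), , drop = FALSE]
    if (padded)
      dat <- rbind(dat, matrix(0, nrow = nt - take, ncol = nc))
    j <- j + 1L
    trials[[j]] <- structure(
      list(data = dat,
           label = r$values[i],
           repetition = recording$repetition[s],
           subject = recording$subject,
           padded = padded),
      class = "emg_trial")
  }
  trials
}

#' Slice a trial into sliding windows
#'
#' Windows are taken at offsets `0, S, 2S, ...`; the number of windows is
#' `Nf = floor((NT - W)/S) + 1`.  With the DB1 defaults (500-sample trial,
#' 20-sample window, stride = window) this yields 25 windows and, together
#' with [build_feature_tensor()], the 25 x 5 x 10 per-trial feature shape.
#'
#' @param trial an `emg_trial` from [extract_trials()].
#' @param wspec a [window_spec()].
#' @return object of class `raw_windows`: list with `data`
#'   (`Nf x W x C` array), `label`, `subject`, `repetition`.
#' @export
slide_windows <- function(trial, wspec = window_spec()) {
  stopifnot(inherits(trial, "emg_trial"), inherits(wspec, "window_spec"))
  nt <- nrow(trial$data)
  w <- wspec$window_samples
  s <- wspec$stride_samples
  if (w > nt)
    stop("slide_windows: window (", w, " samples) longer than trial (",
         nt, " samples)")
  nf <- (nt - w) %/% s + 1L
  nc <- ncol(trial$data)
  out <- array(0, dim = c(nf, w, nc))
  for (k in seq_len(nf)) {
    off <- (k - 1L) * s
    out[k, , ] <- trial$data[(off + 1L):(off + w), ]
  }
  structure(
    list(data = out, label = trial$label, subject = trial$subject,
         repetition = trial$repetition),
    class = "raw_windows")
}

#' Dataset bookkeeping summary
#'
#' Total pattern count `N = S * Na * R` for `S` subjects, `Na` gestures and
#' `R` repetitions; for NinaPro DB1, `27 * 52 * 10 = 14040`.
#'
#' @param S subject count.
#' @param Na gesture count (set `include_rest = TRUE` to count the rest
#'   class as an extra gesture).
#' @param R repetitions per gesture per subject.
#' @param include_rest whether the rest class enters the gesture count.
#' @return list with `S`, `Na`, `R`, `N`, `per_subject`.
#' @export
dataset_summary <- function(S, Na, R, include_rest = FALSE) {
  if (S < 1 || Na < 1 || R < 1)
    stop("dataset_summary: counts must be positive")
  na_eff <- Na + as.integer(include_rest)
  per_subject <- na_eff * R
  list(S = S, Na = na_eff, R = R, N = S * per_subject,
       per_subject = per_subject)
}
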