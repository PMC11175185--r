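# Shared fixtures: everything is generated in code at test time.

# small synthetic world: 3 classes, few repetitions, short activations
tiny_config <- function(n_classes = 3L, n_repetitions = 4L, seed = 5L,
                        active = 1, rest = 0.5) {
  synthetic_config(n_classes = n_classes, n_repetitions = n_repetitions,
                   active_duration = active, rest_duration = rest,
                   carrier_band = c(5, 45), seed = seed)
}

# tiny but shape-complete model spec (raw 6 -> 3 -> 2, feature 5 -> 3 -> 2)
tiny_model_spec <- function(n_classes = 3L, ...) {
  model_spec(nf = 3L, window_samples = 6L, n_channels = 2L,
             n_classes = n_classes, conv_filters = 4L,
             raw_kernels = c(2L, 2L), raw_strides = c(2L, 1L),
             inner_units = 3L, bilstm_units = 3L, dense_units = 5L,
             dropout_conv = 0, dropout_dense = 0, l2 = 0, ...)
}

random_raw_windows <- function(nf = 4L, w = 20L, nc = 3L, label = 1L) {
  structure(
    list(data = array(stats::rnorm(nf * w * nc), dim = c(nf, w, nc)),
         label = label, subject = 1L, repetition = 1L),
    class = "raw_windows")
}

# naive per-sample loop oracles for the five time-domain features
naive_mav <- function(x) { s <- 0; for (v in x) s <- s + abs(v); s / length(x) }
naive_rms <- function(x) { s <- 0; for (v in x) s <- s + v^2; sqrt(s / length(x)) }
naive_wl <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s
}
naive_zc <- function(x, thr = 0) {
  n <- 0L
  for (i in seq_len(length(x) - 1))
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= thr) n <- n + 1L
  n
}
naive_ssc <- function(x, thr = 0) {
  n <- 0L
  for (i in 2:(length(x) - 1)) {
    v <- (x[i] - x[i - 1]) * (x[i] - x[i + 1])
    hit <- if (thr > 0) v >= thr else v > 0
    if (hit) n <- n + 1L
  }
  n
}

# random gate-wise LSTM cell for oracle tests
random_cell <- function(d, h) {
  m <- function(r, c) matrix(stats::rnorm(r * c, sd = 0.5), r, c)
  list(W_c = m(h, d), U_c = m(h, h), b_c = stats::rnorm(h),
       W_i = m(h, d), U_i = m(h, h), b_i = stats::rnorm(h),
       W_f = m(h, d), U_f = m(h, h), b_f = stats::rnorm(h),
       W_o = m(h, d), U_o = m(h, h), b_o = stats::rnorm(h))
}

python_available <- function() {
  nzchar(Sys.which("python"))
}

# write a MAT v5 fixture via scipy (independent writer); returns path or NULL
write_mat_fixture <- function(path, n = 60L, channels = 10L,
                              compress = FALSE, drop_stimulus = FALSE) {
  if (!python_available()) return(NULL)
  script <- sprintf("
import numpy as np
from scipy.io import savemat
rng = np.random.default_rng(0)
d = {'emg': rng.normal(size=(%d, %d)),
     'repetition': np.repeat([1.0, 2.0], %d).reshape(-1, 1),
     'subject': np.array([[3.0]])}
%s
savemat(%s, d, do_compression=%s)
", n, channels, n %/% 2L,
    if (drop_stimulus) "" else
      sprintf("d['stimulus'] = np.tile(np.repeat([0.0, 1.0], %d), 2)[:%d].reshape(-1, 1)",
              n %/% 4L, n),
    deparse(path), if (compress) "True" else "False")
  status <- system2("python", "-", input = script, stdout = FALSE,
                    stderr = FALSE)
  if (status == 0L && file.exists(path)) path else NULL
}
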