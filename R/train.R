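#' Training configuration
#'
#' Defaults follow the published protocol: Adam (beta1 = 0.9,
#' beta2 = 0.999), batch size 64, base learning rate 1e-4 held for the
#' first 70 epochs then dropped by a factor 0.1, 500 epochs.  Desk-scale
#' runs override `epochs`, `batch_size` and `base_lr`.
#'
#' @param batch_size trials per gradient step.
#' @param base_lr initial learning rate.
#' @param lr_drop_epoch first epoch (0-based) at which the rate drops.
#' @param lr_drop_factor multiplicative drop factor in `(0, 1]`.
#' @param lr_repeat_drops if `TRUE` the drop repeats every
#'   `lr_drop_epoch` epochs; default is a single drop.
#' @param epochs training epochs.
#' @param beta1,beta2 Adam moment decay rates.
#' @param seed RNG seed for shuffling, dropout and initialization.
#' @param verbose print per-epoch progress.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, base_lr = 1e-4,
                         lr_drop_epoch = 70L, lr_drop_factor = 0.1,
                         lr_repeat_drops = FALSE, epochs = 500L,
                         beta1 = 0.9, beta2 = 0.999, seed = 1L,
                         verbose = FALSE) {
  if (batch_size < 1L) stop("train_config: batch_size must be >= 1")
  if (lr_drop_factor <= 0 || lr_drop_factor > 1)
    stop("train_config: lr_drop_factor must lie in (0, 1]")
  structure(list(batch_size = as.integer(batch_size), base_lr = base_lr,
                 lr_drop_epoch = as.integer(lr_drop_epoch),
                 lr_drop_factor = lr_drop_factor,
                 lr_repeat_drops = lr_repeat_drops,
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

#' Step-decay learning-rate schedule
#'
#' The base rate is held for the first `lr_drop_epoch` epochs; thereafter
#' it is multiplied by `lr_drop_factor` once (default) or once per
#' completed `lr_drop_epoch`-wide interval (`lr_repeat_drops = TRUE`).
#'
#' @param epoch 0-based epoch index.
#' @param config a [train_config()].
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config) {
  if (epoch < 0) stop("lr_schedule: epoch must be >= 0")
  if (epoch < config$lr_drop_epoch) return(config$base_lr)
  drops <- if (config$lr_repeat_drops)
    (epoch %/% config$lr_drop_epoch) else 1L
  config$base_lr * config$lr_drop_factor^drops
}

#' Assemble network inputs from a list of trials
#'
#' Applies the per-trial part of the pipeline: optional Z-score
#' normalization, sliding-window segmentation and time-domain feature
#' extraction, stacking everything into the batched arrays consumed by the
#' model.
#'
#' @param trials list of `emg_trial` objects.
#' @param wspec a [window_spec()].
#' @param fconfig a [feature_config()].
#' @param normalizer optional [fit_normalizer()] statistics applied to each
#'   trial before windowing.
#' @return list with `Xf` (B, Nf, 5, C), `Xr` (B, Nf, W, C), `y` (labels),
#'   `subject` and `repetition` vectors.
#' @export
prepare_trials <- function(trials, wspec = window_spec(),
                           fconfig = feature_config(), normalizer = NULL) {
  if (!length(trials)) stop("prepare_trials: empty trial list")
  b <- length(trials)
  nf <- wspec$Nf; w <- wspec$window_samples
  nc <- ncol(trials[[1L]]$data)
  Xr <- array(0, dim = c(b, nf, w, nc))
  Xf <- array(0, dim = c(b, nf, 5L, nc))
  y <- integer(b); subj <- integer(b); repn <- integer(b)
  for (i in seq_len(b)) {
    tr <- trials[[i]]
    if (!is.null(normalizer)) tr$data <- zscore(tr$data, normalizer)
    rw <- slide_windows(tr, wspec)
    Xr[i, , , ] <- rw$data
    Xf[i, , , ] <- build_feature_tensor(rw, fconfig)$data
    y[i] <- tr$label; subj[i] <- tr$subject; repn[i] <- tr$repetition
  }
  list(Xf = Xf, Xr = Xr, y = y, subject = subj, repetition = repn)
}

#' Train a fusion model
#'
#' Mini-batch Adam training with the step-decay schedule.  Each window of a
#' trial inherits the trial label; the loss is the mean per-window
#' cross-entropy plus the L2 penalty on conv/dense kernels.  History
#' records per-epoch training loss, window-level training accuracy and
#' (when validation data is given) trial-level validation accuracy.
#'
#' @param model a `fusion_model` from [build_dual_stream()] or
#'   [build_single_stream()].
#' @param train_prep training inputs from [prepare_trials()].
#' @param val_prep optional validation inputs.
#' @param config a [train_config()].
#' @return list with the trained `model` and a `history` data.frame.
#' @export
train_model <- function(model, train_prep, val_prep = NULL,
                        config = train_config()) {
  if (!length(train_prep$y)) stop("train_model: empty training set")
  spec <- model$spec
  b_all <- length(train_prep$y)
  k <- spec$n_classes
  l2_names <- grep("^(fc|rc|d)[0-9]_W$", names(model$params), value = TRUE)
  set.seed(config$seed)
  opt <- adam_new(model$params)
  hist <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                     train_window_acc = numeric(0), val_acc = numeric(0))
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_schedule(epoch, config)
    ord <- sample.int(b_all)
    ep_loss <- 0; ep_correct <- 0; ep_windows <- 0
    for (start in seq(1L, b_all, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, b_all)]
      Xr <- train_prep$Xr[idx, , , , drop = FALSE]
      Xf <- if (model$type == "dual")
        train_prep$Xf[idx, , , , drop = FALSE]
      yb <- train_prep$y[idx]
      fw <- model_forward(model, Xf, Xr, training = TRUE)
      model <- fw$model  # updated BN running stats
      bsz <- length(idx); nfw <- dim(fw$probs)[2L]
      probs <- fw$probs; dim(probs) <- c(bsz * nfw, k)
      ywin <- rep(yb, times = nfw)     # labels broadcast over windows
      Y <- onehot(ywin, k)
      loss <- cross_entropy_loss(probs, Y)
      for (nm in l2_names)
        loss <- loss + spec$l2 * sum(model$params[[nm]]^2)
      if (!is.finite(loss))
        stop("train_model: non-finite loss at epoch ", epoch,
             " (diverged; lower the learning rate)")
      dlogits <- (probs - Y) / nrow(probs)
      grads <- model_backward(model, fw$cache, dlogits)
      for (nm in l2_names)
        grads[[nm]] <- grads[[nm]] + 2 * spec$l2 * model$params[[nm]]
      upd <- adam_step(model$params, grads, opt, lr,
                       config$beta1, config$beta2)
      model$params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + loss * bsz
      ep_correct <- ep_correct + sum(max.col(probs) == ywin)
      ep_windows <- ep_windows + nrow(probs)
    }
    val_acc <- NA_real_
    if (!is.null(val_prep) && length(val_prep$y)) {
      val_acc <- evaluate_model(model, val_prep)$accuracy
    }
    hist <- rbind(hist, data.frame(
      epoch = epoch, lr = lr, loss = ep_loss / b_all,
      train_window_acc = 100 * ep_correct / ep_windows,
      val_acc = val_acc))
    if (config$verbose)
      message(sprintf("epoch %3d  lr %.2g  loss %.4f  win-acc %.1f%%  val %.1f%%",
                      epoch, lr, ep_loss / b_all,
                      100 * ep_correct / ep_windows, val_acc))
  }
  list(model = model, history = hist)
}

#' Per-window class probabilities for one trial
#'
#' @param model a trained `fusion_model`.
#' @param prep a [prepare_trials()] result.
#' @param i trial index within `prep`.
#' @return `Nf x n_classes` matrix; each row is a distribution.
#' @export
predict_trial <- function(model, prep, i = 1L) {
  Xr <- prep$Xr[i, , , , drop = FALSE]
  Xf <- if (model$type == "dual") prep$Xf[i, , , , drop = FALSE]
  fw <- model_forward(model, Xf, Xr, training = FALSE)
  matrix(fw$probs[1L, , ], dim(fw$probs)[2L], dim(fw$probs)[3L])
}

#' Aggregate per-window probabilities into a trial-level label
#'
#' The predicted label is the argmax of the mean probability vector over
#' windows; exact ties break toward the lowest class index.
#'
#' @param window_probs `Nf x K` probability matrix.
#' @return 1-based predicted class index.
#' @export
aggregate_trial <- function(window_probs) {
  if (!nrow(window_probs)) stop("aggregate_trial: need at least one window")
  which.max(colMeans(window_probs))  # which.max takes the first maximum
}

#' Evaluate a model on prepared trials
#'
#' Computes trial-level predictions (window-mean aggregation), the overall
#' accuracy in percent, the per-class accuracy vector and the confusion
#' matrix (true class x predicted class counts); window-level accuracy is
#' reported alongside for diagnostics.
#'
#' @param model a trained `fusion_model`.
#' @param prep a [prepare_trials()] result.
#' @param batch_size forward-pass batch size.
#' @return object of class `eval_report`.
#' @export
evaluate_model <- function(model, prep, batch_size = 64L) {
  n <- length(prep$y)
  if (!n) stop("evaluate_model: no trials to evaluate")
  k <- model$spec$n_classes
  pred <- integer(n); win_correct <- 0; win_total <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    Xr <- prep$Xr[idx, , , , drop = FALSE]
    Xf <- if (model$type == "dual") prep$Xf[idx, , , , drop = FALSE]
    fw <- model_forward(model, Xf, Xr, training = FALSE)
    for (j in seq_along(idx)) {
      wp <- matrix(fw$probs[j, , ], dim(fw$probs)[2L], k)
      pred[idx[j]] <- aggregate_trial(wp)
      win_correct <- win_correct + sum(max.col(wp) == prep$y[idx[j]])
      win_total <- win_total + nrow(wp)
    }
  }
  cm <- matrix(0L, k, k, dimnames = list(true = 1:k, predicted = 1:k))
  for (i in seq_len(n)) cm[prep$y[i], pred[i]] <- cm[prep$y[i], pred[i]] + 1L
  per_class <- ifelse(rowSums(cm) > 0, 100 * diag(cm) / rowSums(cm), NA_real_)
  structure(
    list(accuracy = 100 * sum(pred == prep$y) / n,
         window_accuracy = 100 * win_correct / win_total,
         per_class_accuracy = per_class,
         confusion = cm, n_trials = n, predictions = pred),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d trials: accuracy %.2f%% (window-level %.2f%%)\n",
    x$n_trials, x$accuracy, x$window_accuracy))
  invisible(x)
}

#' Subject-wise training and evaluation
#'
#' Trains and validates an independent model for every subject on that
#' subject's own trials (normalizer fitted on the subject's training
#' trials only), then averages the per-subject accuracies.  Subjects with
#' no validation trials are excluded with a warning.
#'
#' @param dataset list with `train` and `val` trial lists (e.g. from
#'   [generate_dataset()]).
#' @param spec a [model_spec()].
#' @param config a [train_config()].
#' @param wspec,fconfig windowing and feature configuration.
#' @param builder model constructor, [build_dual_stream()] by default.
#' @return list with `reports` (per-subject `eval_report`s) and
#'   `mean_accuracy`.
#' @export
run_subject_wise <- function(dataset, spec, config = train_config(),
                             wspec = window_spec(),
                             fconfig = feature_config(),
                             builder = build_dual_stream) {
  subjects <- sort(unique(vapply(dataset$train, function(t) t$subject, 1)))
  reports <- list()
  for (s in subjects) {
    tr <- Filter(function(t) t$subject == s, dataset$train)
    va <- Filter(function(t) t$subject == s, dataset$val)
    if (!length(va)) {
      warning("run_subject_wise: subject ", s,
              " has no validation trials; excluded")
      next
    }
    norm <- fit_normalizer(lapply(tr, function(t) t$data))
    tr_prep <- prepare_trials(tr, wspec, fconfig, norm)
    va_prep <- prepare_trials(va, wspec, fconfig, norm)
    set.seed(config$seed + s)
    model <- builder(spec)
    fit <- train_model(model, tr_prep, va_prep, config)
    reports[[as.character(s)]] <- evaluate_model(fit$model, va_prep)
  }
  if (!length(reports)) stop("run_subject_wise: no subject had validation data")
  accs <- vapply(reports, function(r) r$accuracy, numeric(1))
  list(reports = reports, mean_accuracy = mean(accs),
       per_subject_accuracy = accs)
}
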