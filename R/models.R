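#' Phase-classifier architecture
#'
#' Two stacked LSTM layers, a rectified-linear fully connected layer with
#' dropout, and a four-way softmax output — one class per gait phase.
#'
#' @param input_dim feature dimension (4 per channel).
#' @param lstm_sizes units of the two LSTM layers.
#' @param fc_size units of the fully connected layer.
#' @param n_classes number of phases (always 4 here).
#' @param dropout dropout probability after the fully connected hidden
#'   layer, in `[0, 1)`.
#' @param sequence_len windows of temporal context per training sequence.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(input_dim, lstm_sizes = c(40, 40), fc_size = 20,
                            n_classes = 4, dropout = 0.5,
                            sequence_len = 10) {
  stopifnot(n_classes == 4L, dropout >= 0, dropout < 1)
  layers <- c(lapply(lstm_sizes, function(u) list(type = "lstm", units = u)),
              list(list(type = "dense", units = fc_size,
                        activation = "relu", dropout = dropout)),
              list(list(type = "dense", units = n_classes,
                        activation = "linear")))
  out <- list(input_dim = input_dim, layers = layers,
              n_classes = n_classes, sequence_len = sequence_len)
  class(out) <- "classifier_spec"
  out
}

#' Angle-predictor architecture
#'
#' A deep LSTM feature extractor (three LSTM layers plus a small projection
#' layer) feeding an LSTM angle predictor (two LSTM layers, a wide
#' rectified-linear layer, and a single linear output), trained end-to-end
#' for the angle `horizon_ms` ahead. The input mode selects which channels
#' are fed: the current angle alone, EMG features plus the angle, or EMG
#' features plus the (one-hot) gait phase plus the angle.
#'
#' @param input_mode one of `"angle_only"`, `"emg_based"`,
#'   `"emg_phase_based"`.
#' @param extractor_sizes four sizes: three LSTM layers + projection units.
#' @param predictor_sizes four sizes: two LSTM layers, a dense layer, and
#'   the 1-unit output.
#' @param horizon_ms prediction horizon (ms).
#' @param sequence_len windows of temporal context per sequence.
#' @param phase_encoding `"onehot"` (default) or `"ordinal"`.
#' @param dropout dropout probability after every fully connected hidden
#'   layer (the extractor projection and the predictor's wide layer).
#' @return object of class `predictor_spec`.
#' @export
predictor_spec <- function(input_mode = c("emg_phase_based", "emg_based",
                                          "angle_only"),
                           extractor_sizes = c(30, 30, 30, 5),
                           predictor_sizes = c(30, 30, 60, 1),
                           horizon_ms = 40, sequence_len = 10,
                           phase_encoding = c("onehot", "ordinal"),
                           dropout = 0.5) {
  input_mode <- match.arg(input_mode)
  phase_encoding <- match.arg(phase_encoding)
  stopifnot(horizon_ms >= 0,
            predictor_sizes[length(predictor_sizes)] == 1L)
  # auxiliary channels (phase, current angle) bypass the EMG feature
  # extractor and join at the predictor stage
  n_aux <- switch(input_mode,
    angle_only = 0L,
    emg_based = 1L,
    emg_phase_based = if (phase_encoding == "onehot") 5L else 2L)
  predictor_layers <- c(
    list(list(type = "lstm", units = predictor_sizes[1], append = n_aux)),
    list(list(type = "lstm", units = predictor_sizes[2])),
    list(list(type = "dense", units = predictor_sizes[3],
              activation = "relu", dropout = dropout)),
    list(list(type = "dense", units = 1L, activation = "linear")))
  layers <- if (input_mode == "angle_only") {
    predictor_layers[[1]]$append <- 0L
    predictor_layers
  } else {
    c(lapply(extractor_sizes[1:3], function(u)
        list(type = "lstm", units = u)),
      list(list(type = "dense", units = extractor_sizes[4],
                activation = "relu")),
      predictor_layers)
  }
  out <- list(input_mode = input_mode, layers = layers,
              horizon_ms = horizon_ms, sequence_len = sequence_len,
              phase_encoding = phase_encoding)
  class(out) <- "predictor_spec"
  out
}

#' Training configuration
#'
#' @param lr Adam learning rate for initial training.
#' @param epochs training epochs.
#' @param batch minibatch size.
#' @param seed integer seed controlling initialisation, shuffling and
#'   dropout; fixed-seed training is reproducible.
#' @param patience early-stopping patience in epochs (0 disables).
#' @param val_frac fraction of sequences held out for early stopping.
#' @param stride train on every `stride`-th sequence; successive windows
#'   overlap heavily, so a stride of 2-3 thins near-duplicate sequences
#'   at little information cost. Prediction always uses every window.
#' @param weight_decay decoupled (AdamW-style) weight-decay coefficient.
#' @param fine_tune_lr reduced learning rate used by [fine_tune()].
#' @param fine_tune_epochs epochs per fine-tuning budget.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, epochs = 50, batch = 64, seed = 1L,
                         patience = 5, val_frac = 0.1, weight_decay = 1e-3,
                         stride = 1L,
                         fine_tune_lr = 1e-4, fine_tune_epochs = 20) {
  stopifnot(epochs >= 1, stride >= 1)
  out <- list(lr = lr, epochs = epochs, batch = batch,
              seed = as.integer(seed), patience = patience,
              val_frac = val_frac, weight_decay = weight_decay,
              stride = as.integer(stride),
              fine_tune_lr = fine_tune_lr,
              fine_tune_epochs = fine_tune_epochs)
  class(out) <- "train_config"
  out
}

as_frame_list <- function(frames) {
  if (inherits(frames, "feature_frame")) list(frames) else frames
}

onehot_phase <- function(phase) {
  m <- matrix(0, length(phase), 4L,
              dimnames = list(NULL, paste0("phase_", PHASES)))
  m[cbind(seq_along(phase), as.integer(phase))] <- 1
  m
}

# Input matrix for the predictor under a given mode.
predictor_inputs <- function(frame, input_mode, phase_encoding = "onehot",
                             phase = NULL) {
  if (is.null(phase)) phase <- frame$phase
  switch(input_mode,
    angle_only = cbind(angle_now = frame$angle_now),
    emg_based = cbind(frame$X, angle_now = frame$angle_now),
    emg_phase_based = {
      ph <- if (phase_encoding == "onehot") onehot_phase(phase)
            else cbind(phase_ord = as.integer(phase))
      cbind(frame$X, ph, angle_now = frame$angle_now)
    })
}

fit_scaler <- function(Z) {
  mu <- colMeans(Z)
  sdv <- apply(Z, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(Z, sc) {
  sweep(sweep(Z, 2, sc$mean), 2, sc$sd, "/")
}

# Stack per-frame sliding sequences into one (D, N, T) cube. Sequences do
# not cross frame boundaries; leading windows are warm-started by
# repeating the first window.
build_sequences <- function(Z_list, sequence_len) {
  cubes <- lapply(Z_list, function(Z) {
    n <- nrow(Z); d <- ncol(Z)
    cube <- array(0, dim = c(d, n, sequence_len))
    for (t in seq_len(sequence_len)) {
      idx <- pmax(1L, seq_len(n) - (sequence_len - t))
      cube[, , t] <- t(Z[idx, , drop = FALSE])
    }
    cube
  })
  n_tot <- sum(vapply(cubes, function(cc) dim(cc)[2], 0))
  d <- dim(cubes[[1]])[1]
  out <- array(0, dim = c(d, n_tot, sequence_len))
  at <- 0L
  for (cc in cubes) {
    n <- dim(cc)[2]
    out[, at + seq_len(n), ] <- cc
    at <- at + n
  }
  out
}

#' Train the LSTM gait-phase classifier
#'
#' @param frames a `feature_frame` or list of them (training trials).
#' @param spec a [classifier_spec()]; defaults to the standard
#'   architecture at the frames' feature dimension.
#' @param cfg a [train_config()].
#' @return object of class `phase_model` with the trained weights, the
#'   feature scaler and the training history.
#' @export
train_phase_classifier <- function(frames, spec = NULL,
                                   cfg = train_config()) {
  frames <- as_frame_list(frames)
  phase_all <- unlist(lapply(frames, function(f) as.integer(f$phase)))
  missing_cls <- setdiff(seq_len(4L), unique(phase_all))
  if (length(missing_cls))
    stop("class(es) absent from training data: ",
         paste(PHASES[missing_cls], collapse = ", "))
  X_all <- do.call(rbind, lapply(frames, `[[`, "X"))
  if (is.null(spec)) spec <- classifier_spec(input_dim = ncol(X_all))
  stopifnot(spec$input_dim == ncol(X_all))
  scaler <- fit_scaler(X_all)
  cube <- build_sequences(lapply(frames, function(f)
    apply_scaler(f$X, scaler)), spec$sequence_len)
  Y <- t(onehot_phase(factor(PHASES[phase_all], levels = PHASES)))
  if (!is.null(cfg$stride) && cfg$stride > 1L) {
    keep <- seq(1, dim(cube)[2], by = cfg$stride)
    cube <- cube[, keep, , drop = FALSE]
    Y <- Y[, keep, drop = FALSE]
  }
  weights0 <- nn_init(spec$layers, spec$input_dim, cfg$seed)
  fit <- nn_train_cpp(spec$layers, weights0, cube, Y, "softmax",
                      list(epochs = cfg$epochs, batch = cfg$batch,
                           lr = cfg$lr, seed = cfg$seed,
                           patience = cfg$patience,
                           val_frac = cfg$val_frac,
                           weight_decay = cfg$weight_decay))
  out <- list(spec = spec, weights = fit$weights, scaler = scaler,
              cfg = cfg, history = fit$history,
              val_history = fit$val_history,
              stopped_epoch = fit$stopped_epoch,
              channels = frames[[1]]$channels)
  class(out) <- "phase_model"
  out
}

#' Classify gait phases
#'
#' @param model a `phase_model`.
#' @param frames a `feature_frame` or list of them.
#' @return list with `phase` (factor, one label per window) and `prob`
#'   (windows x 4 matrix of class probabilities).
#' @export
classify <- function(model, frames) {
  stopifnot(inherits(model, "phase_model"))
  frames <- as_frame_list(frames)
  d <- ncol(frames[[1]]$X)
  if (d != model$spec$input_dim)
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 model$spec$input_dim, d))
  cube <- build_sequences(lapply(frames, function(f)
    apply_scaler(f$X, model$scaler)), model$spec$sequence_len)
  z <- nn_forward_cpp(model$spec$layers, model$weights, cube)
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  prob <- t(sweep(e, 2, colSums(e), "/"))
  colnames(prob) <- PHASES
  list(phase = factor(PHASES[max.col(prob)], levels = PHASES), prob = prob)
}

#' Train the ahead-of-time angle predictor
#'
#' Trains the feature extractor and angle predictor jointly (end-to-end)
#' against the future angle with a mean-squared-error loss.
#'
#' @param frames a `feature_frame` or list of them carrying `angle_now`
#'   and `angle_future`.
#' @param spec a [predictor_spec()].
#' @param cfg a [train_config()].
#' @return object of class `angle_model`.
#' @export
train_angle_predictor <- function(frames, spec = predictor_spec(),
                                  cfg = train_config()) {
  frames <- as_frame_list(frames)
  for (f in frames) {
    if (is.null(f$angle_now) || is.null(f$angle_future) ||
        anyNA(f$angle_future))
      stop("missing angle targets in feature frame")
  }
  Z_list <- lapply(frames, predictor_inputs, input_mode = spec$input_mode,
                   phase_encoding = spec$phase_encoding)
  Z_all <- do.call(rbind, Z_list)
  in_scaler <- fit_scaler(Z_all)
  ang_all <- unlist(lapply(frames, `[[`, "angle_now"))
  ang_scaler <- list(mean = mean(ang_all), sd = max(stats::sd(ang_all), 1e-9))
  cube <- build_sequences(lapply(Z_list, apply_scaler, sc = in_scaler),
                          spec$sequence_len)
  y <- (unlist(lapply(frames, `[[`, "angle_future")) - ang_scaler$mean) /
    ang_scaler$sd
  Y <- matrix(y, nrow = 1)
  if (!is.null(cfg$stride) && cfg$stride > 1L) {
    keep <- seq(1, dim(cube)[2], by = cfg$stride)
    cube <- cube[, keep, , drop = FALSE]
    Y <- Y[, keep, drop = FALSE]
  }
  weights0 <- nn_init(spec$layers, ncol(Z_all), cfg$seed)
  fit <- nn_train_cpp(spec$layers, weights0, cube, Y, "mse",
                      list(epochs = cfg$epochs, batch = cfg$batch,
                           lr = cfg$lr, seed = cfg$seed,
                           patience = cfg$patience,
                           val_frac = cfg$val_frac,
                           weight_decay = cfg$weight_decay))
  out <- list(spec = spec, weights = fit$weights, in_scaler = in_scaler,
              ang_scaler = ang_scaler, cfg = cfg, history = fit$history,
              val_history = fit$val_history,
              stopped_epoch = fit$stopped_epoch,
              input_dim = ncol(Z_all),
              angle_range = range(ang_all))
  class(out) <- "angle_model"
  out
}

#' Predict joint angles ahead of time
#'
#' One prediction per window, at the window end time plus the model's
#' horizon. When `phase_source = "classifier"` the phase channel is taken
#' from a trained classifier's output, making the pipeline fully causal;
#' with `"true_labels"` the recorded labels are used.
#'
#' @param model an `angle_model`.
#' @param frames a `feature_frame` or list of them.
#' @param phase_source `"true_labels"` or `"classifier"`.
#' @param classifier a `phase_model`; required when
#'   `phase_source = "classifier"` and the input mode uses phases.
#' @return list with `angle_pred` (numeric, one per window), `times`
#'   (prediction target times) and `angle_ref` (the recorded future angle).
#' @export
predict_ahead <- function(model, frames,
                          phase_source = c("true_labels", "classifier"),
                          classifier = NULL) {
  stopifnot(inherits(model, "angle_model"))
  phase_source <- match.arg(phase_source)
  frames <- as_frame_list(frames)
  uses_phase <- model$spec$input_mode == "emg_phase_based"
  if (uses_phase && phase_source == "classifier" && is.null(classifier))
    stop("phase_source = \"classifier\" requires a classifier model")
  Z_list <- lapply(frames, function(f) {
    ph <- if (uses_phase && phase_source == "classifier")
      classify(classifier, f)$phase else f$phase
    predictor_inputs(f, model$spec$input_mode, model$spec$phase_encoding,
                     phase = ph)
  })
  if (ncol(Z_list[[1]]) != model$input_dim)
    stop("input dimension mismatch")
  cube <- build_sequences(lapply(Z_list, apply_scaler, sc = model$in_scaler),
                          model$spec$sequence_len)
  z <- nn_forward_cpp(model$spec$layers, model$weights, cube)
  pred <- as.numeric(z) * model$ang_scaler$sd + model$ang_scaler$mean
  list(angle_pred = pred,
       times = unlist(lapply(frames, function(f)
         f$times + model$spec$horizon_ms / 1000)),
       angle_ref = unlist(lapply(frames, `[[`, "angle_future")))
}

# Continue training an existing model's weights on new frames.
continue_training <- function(model, frames, lr, epochs, cfg) {
  frames <- as_frame_list(frames)
  if (inherits(model, "phase_model")) {
    cube <- build_sequences(lapply(frames, function(f)
      apply_scaler(f$X, model$scaler)), model$spec$sequence_len)
    ph <- factor(unlist(lapply(frames, function(f) as.character(f$phase))),
                 levels = PHASES)
    Y <- t(onehot_phase(ph))
    loss <- "softmax"
  } else {
    Z_list <- lapply(frames, predictor_inputs,
                     input_mode = model$spec$input_mode,
                     phase_encoding = model$spec$phase_encoding)
    cube <- build_sequences(lapply(Z_list, apply_scaler,
                                   sc = model$in_scaler),
                            model$spec$sequence_len)
    y <- (unlist(lapply(frames, `[[`, "angle_future")) -
            model$ang_scaler$mean) / model$ang_scaler$sd
    Y <- matrix(y, nrow = 1)
    loss <- "mse"
  }
  fit <- nn_train_cpp(model$spec$layers, model$weights, cube, Y, loss,
                      list(epochs = epochs, batch = cfg$batch, lr = lr,
                           seed = cfg$seed + 1L, patience = 0,
                           val_frac = 0,
                           weight_decay = cfg$weight_decay))
  model$weights <- fit$weights
  model$history <- c(model$history, fit$history)
  model
}

#' Adapt a trained model to a shifted condition by fine-tuning
#'
#' The budgets (in minutes of the new condition) are cumulative: at each
#' step the model carried over from the previous budget is trained
#' further, at a reduced learning rate and with all weights free, on the
#' first `m` minutes of the new data — mirroring a protocol in which
#' another minute of assisted-walking data is added and the decoder is
#' updated. Every budget is evaluated on the same fixed held-out tail
#' (the windows beyond the largest budget) so the points of the
#' adaptation curve are comparable. Budget 0 (the unadapted
#' cross-condition performance) is always included.
#'
#' @param model a `phase_model` or `angle_model` trained on the source
#'   condition.
#' @param new_frames a single time-ordered `feature_frame` from the
#'   shifted condition.
#' @param minutes increasing vector of cumulative data budgets in minutes.
#' @param cfg a [train_config()]; `fine_tune_lr` and `fine_tune_epochs`
#'   are used.
#' @return list with `curve` (data.frame of budget vs metrics), `models`
#'   (adapted model per budget) and `test_windows` (indices of the fixed
#'   held-out tail).
#' @export
fine_tune <- function(model, new_frames, minutes = c(1, 2, 3, 4),
                      cfg = train_config()) {
  stopifnot(inherits(new_frames, "feature_frame"))
  minutes <- sort(minutes)
  wpm <- 60 * 1000 / new_frames$spec$increment_ms
  n <- nrow(new_frames$X)
  max_w <- round(max(minutes) * wpm)
  if (max_w >= n)
    stop("budget exceeds available data: need > ", max_w, " windows, have ",
         n)
  test_idx <- (max_w + 1L):n
  test_frame <- subset_frame(new_frames, test_idx)

  eval_fun <- function(mod) {
    if (inherits(mod, "phase_model")) {
      out <- classify(mod, test_frame)
      classification_report(out$phase, test_frame$phase)
    } else {
      pr <- predict_ahead(mod, test_frame, phase_source = "true_labels")
      regression_report(pr$angle_pred, pr$angle_ref)
    }
  }
  reports <- list(eval_fun(model))
  models <- list(model)
  budgets <- c(0, minutes)
  current <- model
  for (m in minutes) {
    idx <- seq_len(round(m * wpm))
    current <- continue_training(current, subset_frame(new_frames, idx),
                                 lr = cfg$fine_tune_lr,
                                 epochs = cfg$fine_tune_epochs, cfg = cfg)
    models[[length(models) + 1L]] <- current
    reports[[length(reports) + 1L]] <- eval_fun(current)
  }
  curve <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    if (!is.null(r$acc)) {
      data.frame(budget_min = budgets[i], metric = "acc", value = r$acc)
    } else {
      data.frame(budget_min = budgets[i],
                 metric = c("r_value", "rmse", "nrmse"),
                 value = c(r$r_value, r$rmse, r$nrmse))
    }
  }))
  list(curve = curve, reports = reports, models = models,
       test_windows = test_idx)
}
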