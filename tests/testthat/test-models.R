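# Model tests train tiny networks on short trials; the heavier end-to-end
# behaviour (accuracy levels, ablation ordering, adaptation) lives in
# test-acceptance.R.

small_frame <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      trial <- generate_trial(sim_config(duration_s = 40, seed = 202))
      cache <<- build_feature_frame(trial, channels = selected_channels)
    }
    cache
  }
})

fast_cfg <- function(seed = 1, epochs = 5)
  train_config(epochs = epochs, seed = seed, patience = 0, val_frac = 0)

test_that("analytic gradients match finite differences through the whole stack", {
  set.seed(42)
  layers <- list(list(type = "lstm", units = 4),
                 list(type = "dense", units = 3, activation = "relu"),
                 list(type = "lstm", units = 3, append = 2L),
                 list(type = "dense", units = 1, activation = "linear"))
  D <- 7; Tn <- 4; B <- 3
  w <- gaitdecode:::nn_init(layers, D, 7L)
  X <- array(rnorm(D * B * Tn), c(D, B, Tn))
  Y <- matrix(rnorm(B), 1, B)
  res <- gaitdecode:::nn_loss_grad_cpp(layers, w, X, Y, "mse")
  eps <- 1e-5
  for (li in seq_along(w)) for (nm in names(w[[li]])) {
    G <- res$grads[[li]][[nm]]
    for (j in seq_len(min(length(w[[li]][[nm]]), 6))) {
      wp <- w; wp[[li]][[nm]][j] <- wp[[li]][[nm]][j] + eps
      wm <- w; wm[[li]][[nm]][j] <- wm[[li]][[nm]][j] - eps
      fd <- (gaitdecode:::nn_loss_grad_cpp(layers, wp, X, Y, "mse")$loss -
             gaitdecode:::nn_loss_grad_cpp(layers, wm, X, Y, "mse")$loss) /
        (2 * eps)
      expect_lt(abs(fd - G[j]) / max(1e-6, abs(fd) + abs(G[j])), 1e-3)
    }
  }

  # softmax head
  layers2 <- list(list(type = "lstm", units = 4),
                  list(type = "dense", units = 4, activation = "linear"))
  w2 <- gaitdecode:::nn_init(layers2, 5L, 3L)
  X2 <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  Y2 <- diag(4)[, c(1, 2, 3)]
  res2 <- gaitdecode:::nn_loss_grad_cpp(layers2, w2, X2, Y2, "softmax")
  for (li in seq_along(w2)) for (nm in names(w2[[li]])) {
    G <- res2$grads[[li]][[nm]]
    for (j in seq_len(min(length(w2[[li]][[nm]]), 5))) {
      wp <- w2; wp[[li]][[nm]][j] <- wp[[li]][[nm]][j] + eps
      wm <- w2; wm[[li]][[nm]][j] <- wm[[li]][[nm]][j] - eps
      fd <- (gaitdecode:::nn_loss_grad_cpp(layers2, wp, X2, Y2,
                                           "softmax")$loss -
             gaitdecode:::nn_loss_grad_cpp(layers2, wm, X2, Y2,
                                           "softmax")$loss) / (2 * eps)
      expect_lt(abs(fd - G[j]) / max(1e-6, abs(fd) + abs(G[j])), 1e-3)
    }
  }
})

test_that("classifier probabilities are normalised and training is seeded", {
  fr <- small_frame()
  m <- train_phase_classifier(fr, cfg = fast_cfg())
  out <- classify(m, fr)
  expect_equal(unname(rowSums(out$prob)), rep(1, nrow(out$prob)),
               tolerance = 1e-6)
  expect_length(out$phase, nrow(fr$X))

  m2 <- train_phase_classifier(fr, cfg = fast_cfg())
  out2 <- classify(m2, fr)
  expect_identical(out$prob, out2$prob)   # same seed, same machine

  m3 <- train_phase_classifier(fr, cfg = fast_cfg(seed = 2))
  expect_false(identical(classify(m3, fr)$prob, out$prob))

  # training loss decreases
  m4 <- train_phase_classifier(fr, cfg = fast_cfg(epochs = 8))
  expect_lt(tail(m4$history, 1), m4$history[1])
})

test_that("degenerate classifier inputs raise informative errors", {
  fr <- small_frame()
  fr_no_ic <- subset_frame(fr, which(fr$phase != "IC"))
  expect_error(train_phase_classifier(fr_no_ic, cfg = fast_cfg()), "IC")

  m <- train_phase_classifier(fr, cfg = fast_cfg())
  fr_bad <- fr
  fr_bad$X <- fr$X[, 1:8]
  expect_error(classify(m, fr_bad), "dimension mismatch")
})

test_that("constant features still yield valid probabilities", {
  fr <- small_frame()
  m <- train_phase_classifier(fr, cfg = fast_cfg())
  fr0 <- fr
  fr0$X[] <- 0
  out <- classify(m, fr0)
  expect_true(all(is.finite(out$prob)))
  expect_equal(unname(rowSums(out$prob)), rep(1, nrow(out$prob)),
               tolerance = 1e-6)
})

test_that("shuffled labels leave no signal beyond class priors", {
  fr <- small_frame()
  n <- nrow(fr$X); k <- floor(n * 0.7)
  train <- subset_frame(fr, 1:k)
  test <- subset_frame(fr, (k + 1):n)
  set.seed(7)
  train$phase <- sample(train$phase)
  m <- train_phase_classifier(train, cfg = fast_cfg(epochs = 6))
  acc <- classification_report(classify(m, test)$phase, test$phase)$acc
  expect_lt(acc, 0.45)   # at most the majority-class rate
})

test_that("frames shorter than the sequence length are warm-started", {
  fr <- small_frame()
  m <- train_phase_classifier(fr, cfg = fast_cfg())
  tiny <- subset_frame(fr, 1:4)    # < sequence_len
  out <- classify(m, tiny)
  expect_length(out$phase, 4)
})

test_that("the zero-horizon copy task is solved almost exactly", {
  trial <- generate_trial(sim_config(duration_s = 60, seed = 77))
  fr <- build_feature_frame(trial, channels = "TA", horizon_ms = 0)
  m <- train_angle_predictor(fr, spec = predictor_spec(
    input_mode = "angle_only", horizon_ms = 0),
    cfg = train_config(epochs = 25, seed = 1, patience = 0, val_frac = 0))
  pr <- predict_ahead(m, fr)
  expect_lt(rmse(pr$angle_pred, fr$angle_now), 0.5)
})

test_that("the predictor bookkeeping and input validation hold", {
  fr <- small_frame()
  m <- train_angle_predictor(fr, spec = predictor_spec(), cfg = fast_cfg())
  pr <- predict_ahead(fr = fr, model = m, phase_source = "true_labels")
  expect_length(pr$angle_pred, nrow(fr$X))
  expect_true(all(is.finite(pr$angle_pred)))
  rng <- range(fr$angle_now)
  expect_true(all(pr$angle_pred > rng[1] - 10 &
                  pr$angle_pred < rng[2] + 10))

  expect_error(predict_ahead(m, fr, phase_source = "classifier"),
               "requires a classifier")

  fr_bad <- fr
  fr_bad$angle_future <- NULL
  expect_error(train_angle_predictor(fr_bad, cfg = fast_cfg()),
               "missing angle targets")
})

test_that("a perfectly agreeing classifier reproduces true-label predictions", {
  fr <- small_frame()
  m <- train_angle_predictor(fr, spec = predictor_spec(), cfg = fast_cfg())
  cls <- train_phase_classifier(fr, cfg = fast_cfg(epochs = 8))
  out <- classify(cls, fr)
  agree <- out$phase == fr$phase
  pr_true <- predict_ahead(m, fr, phase_source = "true_labels")
  pr_cls <- predict_ahead(m, fr, phase_source = "classifier",
                          classifier = cls)
  # wherever the classifier agrees with the labels over a whole input
  # sequence the two prediction paths coincide
  L <- m$spec$sequence_len
  ok <- vapply(seq_along(agree), function(i)
    all(agree[max(1, i - L + 1):i]), logical(1))
  expect_equal(pr_cls$angle_pred[ok], pr_true$angle_pred[ok])
})

test_that("fine-tuning starts from the unadapted model and respects budgets", {
  fr <- small_frame()
  n <- nrow(fr$X)
  m <- train_phase_classifier(subset_frame(fr, 1:floor(n / 2)),
                              cfg = fast_cfg())
  new_fr <- subset_frame(fr, (floor(n / 2) + 1):n)
  # ~0.2 minutes of windows available; ask for a feasible small budget
  ft <- fine_tune(m, new_fr, minutes = 0.1,
                  cfg = train_config(epochs = 2, fine_tune_epochs = 2,
                                     seed = 1, patience = 0, val_frac = 0))
  base_acc <- ft$curve$value[ft$curve$budget_min == 0]
  tail_frame <- subset_frame(new_fr, ft$test_windows)
  direct <- classification_report(classify(m, tail_frame)$phase,
                                  tail_frame$phase)$acc
  expect_equal(base_acc, direct)

  expect_error(fine_tune(m, new_fr, minutes = 60,
                         cfg = train_config(epochs = 1)),
               "budget exceeds")
})
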