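#' Pearson correlation between predicted and reference traces
#'
#' `cov(pred, ref) / (sd(pred) * sd(ref))` with the population (divide by
#' n) convention used consistently in numerator and denominator, so the
#' convention cancels.
#'
#' @param pred,ref equal-length numeric vectors (length >= 2).
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(pred) >= 2)
  cp <- pred - mean(pred)
  cr <- ref - mean(ref)
  sp <- sqrt(mean(cp^2))
  sr <- sqrt(mean(cr^2))
  if (sp == 0 || sr == 0) stop("zero variance input")
  mean(cp * cr) / (sp * sr)
}

#' Root-mean-square error
#'
#' @param pred,ref equal-length numeric vectors.
#' @return RMSE in the units of the inputs (degrees for angles).
#' @export
rmse <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(pred) >= 1)
  sqrt(mean((pred - ref)^2))
}

#' Range-normalised RMSE
#'
#' RMSE divided by the range of the *predicted* trace (the convention used
#' throughout this package); set `use_reference_range = TRUE` to normalise
#' by the reference range instead. Returned as a fraction; multiply by 100
#' to report percent.
#'
#' @param pred,ref equal-length numeric vectors.
#' @param use_reference_range normalise by the reference range.
#' @return NRMSE as a fraction.
#' @export
nrmse <- function(pred, ref, use_reference_range = FALSE) {
  base <- if (use_reference_range) ref else pred
  rng <- diff(range(base))
  if (rng == 0) stop("constant trace: NRMSE undefined")
  rmse(pred, ref) / rng
}

#' Classification metrics report
#'
#' @param pred,truth factors over the four phases.
#' @return list with `acc`, `confusion` (4 x 4 counts, rows = truth),
#'   `per_phase_acc` and `n`.
#' @export
classification_report <- function(pred, truth) {
  pred <- factor(pred, levels = PHASES)
  truth <- factor(truth, levels = PHASES)
  stopifnot(length(pred) == length(truth))
  confusion <- table(truth = truth, pred = pred)
  acc <- sum(diag(confusion)) / length(truth)
  per_phase <- diag(confusion) / pmax(rowSums(confusion), 1L)
  list(acc = acc, confusion = unclass(confusion),
       per_phase_acc = per_phase, n = length(truth))
}

#' Regression metrics report
#'
#' @param pred,ref predicted and reference angle traces (degrees).
#' @return list with `r_value`, `rmse` (degrees), `nrmse` (fraction) and
#'   `n`.
#' @export
regression_report <- function(pred, ref) {
  list(r_value = pearson_r(pred, ref), rmse = rmse(pred, ref),
       nrmse = nrmse(pred, ref), n = length(pred))
}

#' One-way analysis of variance
#'
#' Closed-form between/within mean-square ratio and its F tail
#' probability.
#'
#' @param groups list of numeric vectors, each with >= 2 values.
#' @return list with `F`, `p`, `df` (between, within).
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 values")
  all_v <- unlist(groups)
  grand <- mean(all_v)
  means <- vapply(groups, mean, 0)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1L
  df_w <- length(all_v) - length(groups)
  msb <- ssb / df_b
  msw <- ssw / df_w
  f <- if (msw == 0) {
    if (msb == 0) 0 else Inf
  } else msb / msw
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  list(F = f, p = p, df = c(between = df_b, within = df_w))
}

#' Leave-one-trial-out fold plan
#'
#' Every (subject, trial) pair is a test fold; training uses the subject's
#' other trials plus all trials of all other subjects, so each trial is
#' tested exactly once.
#'
#' @param subject subject id per trial.
#' @return list of folds, each with `test` (one index) and `train`.
#' @export
loo_folds <- function(subject) {
  subject <- as.character(subject)
  if (length(unique(subject)) < 2) stop("need at least 2 subjects")
  if (any(table(subject) < 2)) {
    bad <- names(which(table(subject) < 2))
    stop("subject(s) with a single trial: ", paste(bad, collapse = ", "))
  }
  lapply(seq_along(subject), function(i)
    list(test = i, train = setdiff(seq_along(subject), i)))
}

#' Modified leave-one-out cross-validation
#'
#' Runs the fold plan of [loo_folds()] over a set of per-trial feature
#' frames, training a phase classifier or angle predictor on each fold's
#' training trials and evaluating on the held-out trial.
#'
#' @param frames list of `feature_frame`s, one per trial.
#' @param subject subject id per frame.
#' @param task `"phase"` or `"angle"`.
#' @param spec optional [classifier_spec()] / [predictor_spec()].
#' @param cfg a [train_config()].
#' @return list with `folds` (per-fold metric reports) and `summary`
#'   (mean and sd of the headline metric).
#' @export
loo_cv <- function(frames, subject, task = c("phase", "angle"),
                   spec = NULL, cfg = train_config()) {
  task <- match.arg(task)
  stopifnot(length(frames) == length(subject))
  folds <- loo_folds(subject)
  reports <- lapply(seq_along(folds), function(k) {
    fold <- folds[[k]]
    train <- frames[fold$train]
    test <- frames[[fold$test]]
    if (task == "phase") {
      model <- train_phase_classifier(train, spec = spec, cfg = cfg)
      out <- classify(model, test)
      rep <- classification_report(out$phase, test$phase)
    } else {
      model <- train_angle_predictor(
        train, spec = if (is.null(spec)) predictor_spec() else spec,
        cfg = cfg)
      pr <- predict_ahead(model, test, phase_source = "true_labels")
      rep <- regression_report(pr$angle_pred, pr$angle_ref)
    }
    rep$fold_id <- k
    rep$subject <- subject[fold$test]
    rep
  })
  key <- if (task == "phase") "acc" else "rmse"
  vals <- vapply(reports, `[[`, 0, key)
  list(folds = reports,
       summary = c(mean = mean(vals), sd = stats::sd(vals)),
       metric = key)
}

split_frame_halves <- function(frame, split = 0.5) {
  n <- nrow(frame$X)
  k <- floor(n * split)
  list(train = subset_frame(frame, seq_len(k)),
       test = subset_frame(frame, (k + 1L):n))
}

#' Cross-condition degradation experiment
#'
#' Quantifies how a condition shift (exoskeleton assistance) degrades the
#' decoder: trains the phase classifier and the angle predictor on each
#' condition's first half and evaluates on each condition's second half,
#' filling the full 2 x 2 train-condition by test-condition table for
#' both models. The predictor is evaluated with the true phase labels as
#' input, isolating the predictor from classifier errors.
#'
#' @param pair list with `noExo` and `exo` `feature_frame`s (one trial
#'   each, time-ordered).
#' @param cfg a [train_config()].
#' @param cls_spec,pred_spec optional architecture overrides.
#' @return list with `classifier_acc` (2 x 2 matrix, rows = training
#'   condition), `predictor_rmse`, `predictor_r`, `predictor_nrmse`
#'   (2 x 2 matrices) and the per-cell reports.
#' @export
degradation_experiment <- function(pair, cfg = train_config(),
                                   cls_spec = NULL, pred_spec = NULL) {
  stopifnot(all(c("noExo", "exo") %in% names(pair)))
  conds <- c("noExo", "exo")
  halves <- lapply(pair[conds], split_frame_halves)
  cls_models <- lapply(conds, function(cd)
    train_phase_classifier(halves[[cd]]$train, spec = cls_spec, cfg = cfg))
  names(cls_models) <- conds
  prd_models <- lapply(conds, function(cd)
    train_angle_predictor(
      halves[[cd]]$train,
      spec = if (is.null(pred_spec)) predictor_spec() else pred_spec,
      cfg = cfg))
  names(prd_models) <- conds

  acc <- r_m <- rmse_m <- nrmse_m <-
    matrix(NA_real_, 2, 2, dimnames = list(train = conds, test = conds))
  cls_reports <- prd_reports <- list()
  for (tr in conds) for (te in conds) {
    test <- halves[[te]]$test
    out <- classify(cls_models[[tr]], test)
    crep <- classification_report(out$phase, test$phase)
    acc[tr, te] <- crep$acc
    pr <- predict_ahead(prd_models[[tr]], test,
                        phase_source = "true_labels")
    rrep <- regression_report(pr$angle_pred, pr$angle_ref)
    r_m[tr, te] <- rrep$r_value
    rmse_m[tr, te] <- rrep$rmse
    nrmse_m[tr, te] <- rrep$nrmse
    cls_reports[[paste(tr, te, sep = "->")]] <- crep
    prd_reports[[paste(tr, te, sep = "->")]] <- rrep
  }
  list(classifier_acc = acc, predictor_r = r_m, predictor_rmse = rmse_m,
       predictor_nrmse = nrmse_m,
       classifier_reports = cls_reports, predictor_reports = prd_reports,
       classifier_models = cls_models, predictor_models = prd_models)
}

#' Fine-tuning adaptation curve
#'
#' Wraps [fine_tune()] for both the classifier and the predictor: models
#' trained on the unassisted condition are adapted with growing budgets of
#' assisted-condition data and evaluated on a fixed held-out tail of the
#' assisted trial. A within-condition ceiling (a model trained directly on
#' the assisted adaptation data) is evaluated on the same tail.
#'
#' @param pair list with `noExo` and `exo` `feature_frame`s; the `exo`
#'   frame must be long enough for the largest budget plus a test tail.
#' @param minutes cumulative adaptation budgets in minutes.
#' @param cfg a [train_config()].
#' @param tasks which models to adapt: subset of `c("phase", "angle")`.
#' @return list with `curve` (tidy data.frame: task, budget_min, metric,
#'   value), `ceiling` (within-condition reference per task) and the
#'   underlying [fine_tune()] results.
#' @export
adaptation_curve <- function(pair, minutes = c(1, 2, 3, 4),
                             cfg = train_config(),
                             tasks = c("phase", "angle")) {
  stopifnot(all(c("noExo", "exo") %in% names(pair)))
  exo <- pair$exo
  wpm <- 60 * 1000 / exo$spec$increment_ms
  max_w <- round(max(minutes) * wpm)
  if (max_w >= nrow(exo$X)) stop("insufficient assisted-condition data")
  adapt_part <- subset_frame(exo, seq_len(max_w))
  tail_part <- subset_frame(exo, (max_w + 1L):nrow(exo$X))

  out_curve <- list(); details <- list(); ceiling <- list()
  if ("phase" %in% tasks) {
    base <- train_phase_classifier(pair$noExo, cfg = cfg)
    ft <- fine_tune(base, exo, minutes = minutes, cfg = cfg)
    ceil_model <- train_phase_classifier(adapt_part, cfg = cfg)
    ceil_rep <- classification_report(classify(ceil_model, tail_part)$phase,
                                      tail_part$phase)
    ceiling$phase <- ceil_rep
    cv <- ft$curve; cv$task <- "phase"
    out_curve[[length(out_curve) + 1L]] <- cv
    details$phase <- ft
  }
  if ("angle" %in% tasks) {
    base <- train_angle_predictor(pair$noExo, cfg = cfg)
    ft <- fine_tune(base, exo, minutes = minutes, cfg = cfg)
    ceil_model <- train_angle_predictor(adapt_part, cfg = cfg)
    pr <- predict_ahead(ceil_model, tail_part, phase_source = "true_labels")
    ceiling$angle <- regression_report(pr$angle_pred, pr$angle_ref)
    cv <- ft$curve; cv$task <- "angle"
    out_curve[[length(out_curve) + 1L]] <- cv
    details$angle <- ft
  }
  list(curve = do.call(rbind, out_curve), ceiling = ceiling,
       details = details)
}
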