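test_that("the correlation metric honours its identities and worked value", {
  set.seed(1)
  x <- rnorm(50)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.9827,
               tolerance = 1e-4)
  expect_error(pearson_r(rep(1, 10), x[1:10]), "zero variance")
  # agrees with the standard sample correlation (the population
  # convention cancels between numerator and denominator)
  y <- rnorm(50)
  expect_equal(pearson_r(x, y), cor(x, y))
})

test_that("error metrics follow their closed forms", {
  set.seed(2)
  ref <- rnorm(40)
  expect_equal(rmse(ref + 2, ref), 2)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  pred <- c(0, 40)
  expect_equal(nrmse(pred, pred + 2), 2 / 40)
  expect_error(nrmse(rep(1, 5), rnorm(5)), "constant")
  # reference-range variant divides by the reference range instead
  expect_equal(nrmse(c(0, 10), c(0, 20), use_reference_range = TRUE),
               rmse(c(0, 10), c(0, 20)) / 20)
})

test_that("one-way ANOVA matches hand computation and its invariances", {
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  res <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$F, 13.5)
  expect_equal(unname(res$df), c(1, 4))

  # location invariance
  set.seed(3)
  g <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  g_shift <- lapply(g, `+`, 100)
  expect_equal(one_way_anova(g)$F, one_way_anova(g_shift)$F)

  # cross-check against the standard linear-model ANOVA
  vals <- unlist(g)
  grp <- factor(rep(1:3, times = lengths(g)))
  ref <- anova(stats::aov(vals ~ grp))
  expect_equal(one_way_anova(g)$F, ref$`F value`[1])
  expect_equal(one_way_anova(g)$p, ref$`Pr(>F)`[1])

  expect_error(one_way_anova(list(1, c(2, 3))), "at least 2 values")
  expect_error(one_way_anova(list(c(1, 2))), "two groups")
})

test_that("classification reports are consistent counts", {
  truth <- factor(rep(PHASES_TEST, times = c(5, 10, 10, 5)),
                  levels = PHASES_TEST)
  pred <- truth
  pred[1] <- "FF"
  rep <- classification_report(pred, truth)
  expect_equal(rep$n, 30)
  expect_equal(sum(rep$confusion), 30)
  expect_equal(rep$acc, 29 / 30)
  expect_equal(unname(rowSums(rep$confusion)), c(5, 10, 10, 5))
  expect_equal(sum(diag(rep$confusion)) / rep$n, rep$acc)
})

test_that("leave-one-out folds partition the trials exactly", {
  subj <- rep(paste0("S", 1:10), each = 2)
  folds <- loo_folds(subj)
  expect_length(folds, 20)
  tested <- vapply(folds, `[[`, 0L, "test")
  expect_setequal(tested, seq_along(subj))   # each trial tested once
  for (f in folds) {
    expect_length(intersect(f$test, f$train), 0)
    expect_setequal(c(f$test, f$train), seq_along(subj))
  }
  expect_error(loo_folds(c("A", "A", "B")), "single trial")
  expect_error(loo_folds(c("A", "A")), "2 subjects")
})

test_that("leave-one-out cross-validation runs end to end on small trials", {
  frames <- lapply(1:4, function(s) {
    trial <- generate_trial(sim_config(duration_s = 30, seed = 300 + s))
    build_feature_frame(trial, channels = c("TA", "GM"))
  })
  subj <- c("S1", "S1", "S2", "S2")
  cv <- loo_cv(frames, subj, task = "phase",
               cfg = train_config(epochs = 3, seed = 1, patience = 0,
                                  val_frac = 0, stride = 2L))
  expect_length(cv$folds, 4)
  accs <- vapply(cv$folds, `[[`, 0, "acc")
  expect_true(all(is.finite(accs)))
  expect_equal(unname(cv$summary["mean"]), mean(accs))
})

test_that("the degradation experiment fills the full 2x2 condition table", {
  cfg <- sim_config(duration_s = 40, seed = 310)
  pair <- make_condition_pair(cfg, default_exo_shift())
  frames <- lapply(pair, build_feature_frame, channels = c("TA", "GM", "GL"))
  res <- degradation_experiment(
    frames, cfg = train_config(epochs = 3, seed = 1, patience = 0,
                               val_frac = 0, stride = 2L))
  expect_equal(dim(res$classifier_acc), c(2, 2))
  expect_false(anyNA(res$classifier_acc))
  expect_false(anyNA(res$predictor_rmse))
  expect_false(anyNA(res$predictor_r))
  expect_length(res$classifier_reports, 4)
  expect_length(res$predictor_reports, 4)
  # with matched conditions the diagonal is the within-condition reference
  expect_true(all(res$classifier_acc >= 0 & res$classifier_acc <= 1))
})
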