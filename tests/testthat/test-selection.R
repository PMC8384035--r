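test_that("phase areas integrate constants to the phase durations", {
  fs <- 1000
  counts <- c(100, 350, 300, 250)          # 0.1 / 0.35 / 0.30 / 0.25 s
  labels <- make_label_cycle(counts, n_cycles = 3)
  a <- rep(1, length(labels))
  res <- phase_areas(a, labels, fs)
  expect_equal(unname(res$areas), counts / fs, tolerance = 1e-9)
  expect_equal(res$n_cycles, 3)

  expect_equal(unname(phase_areas(rep(0, length(labels)), labels, fs)$areas),
               rep(0, 4))
  expect_error(phase_areas(a[1:50], labels[1:50], fs), "complete cycle")
})

test_that("a single raised-cosine burst integrates to its closed form", {
  # mid-phase burst confined to FF; no EMD, no stride variability
  gains <- matrix(0, 1, 4, dimnames = list("m1", PHASES_TEST))
  gains["m1", "FF"] <- 0.8
  cfg <- sim_config(duration_s = 30, seed = 21, n_muscles = 1,
                    muscles = "m1", burst_gains = gains,
                    cycle_jitter_cv = 0, cycle_amp_cv = 0,
                    timing_jitter_ms = 0, emd_ms = 0)
  cum <- cumsum(c(0, cfg$phase_fractions))[1:4]
  cfg$burst_centers <- matrix(cum + cfg$phase_fractions / 2, 1, 4,
                              dimnames = list("m1", PHASES_TEST))
  trial <- generate_trial(cfg)
  al <- align_trial(trial)
  res <- phase_areas(trial$envelope[1, ], al$phase, trial$rates$fs_emg)
  analytic <- 0.8 * (0.35 * 1.1) / 2     # gain x width_s / 2
  expect_equal(unname(res$areas["FF"]), analytic, tolerance = 0.01)
})

test_that("effects are areas normalised by each muscle's maximum", {
  E <- effect_matrix(rbind(m1 = c(2, 1, 1, 1)))
  expect_equal(unname(E$effects[1, ]), c(1, 0.5, 0.5, 0.5))

  tab <- reference_effect_table()
  expect_equal(max(tab["RF", ]), 1)
  E2 <- effect_matrix(tab)
  expect_true(all(abs(apply(E2$effects, 1, max) - 1) < 1e-12))

  # permuting phases permutes effects identically
  A <- matrix(stats::runif(12, 0.1, 1), 3, 4,
              dimnames = list(paste0("m", 1:3), PHASES_TEST))
  perm <- c(3, 1, 4, 2)
  E_perm <- effect_matrix(A[, perm])
  expect_equal(unname(E_perm$effects), unname(effect_matrix(A)$effects[, perm]))

  expect_error(effect_matrix(rbind(m1 = c(1, 1, 1, 1), m2 = c(0, 0, 0, 0))),
               "m2")
})

test_that("the discard rule retains the published five-muscle subset", {
  sel <- select_muscles(reference_effect_table(), delta = 0.15)
  expect_setequal(sel$retained, c("RF", "TA", "ST", "GM", "GL"))
  expect_setequal(sel$discarded, c("VM", "VL", "SL", "BF"))
  # the subset is stable across the similarity threshold's validity range
  for (delta in c(0.06, 0.10, 0.18)) {
    expect_setequal(select_muscles(reference_effect_table(), delta)$retained,
                    c("RF", "TA", "ST", "GM", "GL"))
  }
})

test_that("coverage repair resurrects phase-dominant muscles", {
  # one dominant muscle per phase: the rule discards all four (each has
  # three mutually similar zero phases), coverage repair re-adds them all
  E <- diag(4)
  rownames(E) <- paste0("m", 1:4)
  sel <- select_muscles(E, delta = 0.15)
  expect_true(all(sel$report$discarded_by_rule))
  expect_setequal(sel$retained, rownames(E))

  # total redundancy: everything discarded, one muscle covers all phases
  E1 <- matrix(1, 4, 4, dimnames = list(paste0("m", 1:4), NULL))
  sel1 <- select_muscles(E1, delta = 0.15)
  expect_equal(sel1$retained, "m1")
  expect_lte(length(sel1$retained), 4)
})

test_that("muscle order only permutes the selection output", {
  tab <- reference_effect_table()
  perm <- c(5, 3, 8, 1, 9, 2, 7, 4, 6)
  sel_p <- select_muscles(tab[perm, ], delta = 0.15)
  sel <- select_muscles(tab, delta = 0.15)
  expect_setequal(sel_p$retained, sel$retained)
})

test_that("the end-to-end effect matrix ranks the phase-dominant muscles highest", {
  trial <- generate_trial(sim_config(duration_s = 30, seed = 33))
  E <- trial_effect_matrix(trial)
  expect_true(all(abs(apply(E$effects, 1, max) - 1) < 1e-12))
  # TA peaks in swing, GM in late stance, as configured
  expect_equal(unname(which.max(E$effects["TA", ])), 4L)
  expect_equal(unname(which.max(E$effects["GM", ])), 3L)
})
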