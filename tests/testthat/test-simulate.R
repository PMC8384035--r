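test_that("generation is reproducible and stream lengths follow floor(duration x rate)", {
  cfg <- sim_config(duration_s = 10, seed = 7)
  t1 <- generate_trial(cfg)
  t2 <- generate_trial(cfg)
  expect_identical(t1, t2)

  expect_equal(ncol(t1$emg), floor(10 * 1111.11))
  expect_equal(length(t1$fsr_heel), 10 * 500)
  expect_equal(length(t1$angle), 10 * 100)
  expect_equal(length(t1$phase_truth), length(t1$fsr_heel))
  expect_true(all(is.finite(t1$angle)))

  cfg60 <- sim_config(duration_s = 60, seed = 1)
  expect_equal(floor(cfg60$duration_s * cfg60$fs_emg), 66666)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration_s = -1), "duration")
  expect_error(sim_config(phase_fractions = c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")
  expect_error(sim_config(fs_emg = 0), "rates")
})

test_that("a gain-only condition shift changes the EMG but not the phase schedule", {
  cfg <- sim_config(duration_s = 15, seed = 3)
  pair <- make_condition_pair(cfg, condition_shift(gain = c(GM = 1.5)))
  expect_identical(pair$noExo$phase_truth, pair$exo$phase_truth)
  expect_false(identical(pair$noExo$emg["GM", ], pair$exo$emg["GM", ]))
  # RMS on the scaled channel grows by the configured factor
  ratio <- sqrt(mean(pair$exo$emg["GM", ]^2)) /
    sqrt(mean(pair$noExo$emg["GM", ]^2))
  expect_equal(ratio, 1.5, tolerance = 0.05)
  # zero shift reproduces the unassisted trial exactly (same parameters)
  same <- make_condition_pair(cfg, condition_shift())
  expect_equal(same$noExo$emg, same$exo$emg)
})

test_that("a phase-duration shift changes mean IC duration by the configured factor", {
  cfg <- sim_config(duration_s = 80, seed = 9, cycle_jitter_cv = 0)
  pair <- make_condition_pair(cfg,
    condition_shift(phase_scale = c(IC = 0.8)))
  ic_dur <- function(trial) {
    r <- rle(as.character(trial$phase_truth))
    mean(r$lengths[r$values == "IC"]) / trial$rates$fs_fsr
  }
  # IC fraction 0.10 scaled by 0.8 and renormalised: 0.08 / 0.98
  expected <- (0.10 * 0.8 / 0.98) / 0.10
  expect_equal(ic_dur(pair$exo) / ic_dur(pair$noExo), expected,
               tolerance = 0.05)
})

test_that("phase fractions measured over many cycles match the configuration", {
  cfg <- sim_config(duration_s = 70, seed = 5)   # >= 50 cycles at 1.1 s
  trial <- generate_trial(cfg)
  tab <- table(trial$phase_truth) / length(trial$phase_truth)
  expect_equal(as.numeric(tab), c(0.10, 0.35, 0.30, 0.25), tolerance = 0.02)
})

test_that("the envelope leads the mechanical schedule by the configured EMD", {
  base <- sim_config(duration_s = 30, seed = 11, cycle_jitter_cv = 0,
                     cycle_amp_cv = 0, timing_jitter_ms = 0, emd_ms = 0,
                     fs_emg = 1000)   # 40 ms = a whole number of samples
  lead <- base; lead$emd_ms <- 40
  e0 <- generate_trial(base)$envelope[1, ]
  e40 <- generate_trial(lead)$envelope[1, ]
  shift <- round(0.040 * 1000)
  n <- length(e0)
  # envelope with EMD equals the zero-EMD envelope advanced by 40 ms
  expect_equal(e40[1:(n - shift)], e0[(shift + 1):n], tolerance = 1e-6)
})

test_that("envelope-vs-angle cross-correlation peak moves with the EMD", {
  peak_lag <- function(emd) {
    cfg <- sim_config(duration_s = 40, seed = 13, cycle_jitter_cv = 0,
                      cycle_amp_cv = 0, timing_jitter_ms = 0,
                      angle_noise_sd = 0, emd_ms = emd)
    trial <- generate_trial(cfg)
    fsa <- trial$rates$fs_angle
    idx <- round((seq_along(trial$angle) - 1) / fsa * trial$rates$fs_emg) + 1
    env <- trial$envelope["TA", pmin(idx, ncol(trial$envelope))]
    cc <- stats::ccf(env, trial$angle, lag.max = 30, plot = FALSE)
    cc$lag[which.max(abs(cc$acf))] / fsa
  }
  # differencing two EMD settings removes the burst-geometry offset
  d <- peak_lag(0) - peak_lag(80)
  expect_equal(d, 0.080, tolerance = 0.011)
})

test_that("foot-switch thresholding recovers the phase schedule", {
  trial <- short_trial()
  lab <- label_phases_from_fsr(trial$fsr_heel, trial$fsr_toe,
                               fs = trial$rates$fs_fsr)
  # away from transitions the recovered labels match the ground truth
  r <- rle(as.character(trial$phase_truth))
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  interior <- unlist(mapply(function(s, e)
    if (e - s > 6) (s + 3):(e - 3) else integer(0),
    starts, ends, SIMPLIFY = FALSE))
  agree <- mean(lab$phase[interior] == trial$phase_truth[interior])
  expect_gt(agree, 0.99)
  expect_gt(length(lab$cycle_starts), 10)
})

test_that("foot-switch state table and degenerate traces behave as documented", {
  lab <- label_phases_from_fsr(c(1, 1, 0, 0), c(0, 1, 1, 0), fs = 500,
                               min_run_ms = 0)
  expect_equal(as.character(lab$phase), c("IC", "FF", "HO", "TO"))

  const <- label_phases_from_fsr(rep(1, 100), rep(1, 100), fs = 500)
  expect_true(all(const$phase == "FF"))
  expect_length(const$cycle_starts, 0)

  expect_error(label_phases_from_fsr(rep(0, 50), rep(0, 50), fs = 500),
               "no contacts")
  expect_error(label_phases_from_fsr(c(1, 0), c(0, 1), fs = 500,
                                     threshold = 1.5),
               "threshold")
})

test_that("short spurious runs are merged into their longer neighbours", {
  heel <- c(rep(1, 50), 0, rep(1, 49), rep(0, 100))
  toe <- c(rep(0, 100), rep(1, 100))
  lab <- label_phases_from_fsr(heel, toe, fs = 500, min_run_ms = 20)
  # the single-sample heel dropout (2 ms) vanishes
  expect_true(all(lab$phase[1:100] == "IC"))
})
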