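#' @useDynLib gaitdecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif splinefun approx sd cor median quantile
#' @importFrom utils head tail
NULL

PHASES <- c("IC", "FF", "HO", "TO")

DEFAULT_MUSCLES <- c("RF", "VM", "VL", "TA", "SL", "ST", "BF", "GM", "GL")

# Per-muscle, per-phase burst gains loosely matching typical lower-limb
# activation patterns during level treadmill walking (quadriceps loading in
# early stance, tibialis anterior in swing, plantarflexors in late stance).
default_burst_gains <- function(muscles = DEFAULT_MUSCLES) {
  ref <- rbind(
    RF = c(1.00, 0.50, 0.25, 0.30),
    VM = c(1.00, 0.35, 0.27, 0.33),
    VL = c(1.00, 0.54, 0.56, 0.53),
    TA = c(0.80, 0.20, 0.20, 1.00),
    SL = c(0.20, 0.90, 1.00, 0.20),
    ST = c(0.75, 0.25, 0.25, 1.00),
    BF = c(1.00, 0.90, 0.95, 0.90),
    GM = c(0.15, 0.60, 1.00, 0.15),
    GL = c(0.45, 0.80, 1.00, 0.20))
  colnames(ref) <- PHASES
  unknown <- setdiff(muscles, rownames(ref))
  out <- matrix(0.5, length(muscles), 4,
                dimnames = list(muscles, PHASES))
  known <- intersect(muscles, rownames(ref))
  out[known, ] <- ref[known, ]
  out
}

#' Simulator configuration
#'
#' Bundles every knob of the synthetic gait generator: the quasi-periodic
#' cycle schedule, the four-phase split of each cycle, per-muscle phase-locked
#' activation bursts, the electromechanical lead of the EMG envelope over the
#' joint angle, and the sampling rates of the three recorded streams.
#'
#' @param duration_s trial length in seconds.
#' @param cycle_mean_s mean gait-cycle duration in seconds.
#' @param cycle_jitter_cv coefficient of variation of cycle durations.
#' @param phase_fractions positive fractions of the cycle spent in
#'   initial contact (IC), flat foot (FF), heel off (HO) and toe off (TO);
#'   must sum to 1.
#' @param n_muscles number of EMG channels.
#' @param muscles channel names; defaults to nine lower-limb muscles.
#' @param burst_centers muscles x 4 matrix of burst centres as fractions of
#'   the cycle; by default each burst sits early in its phase (onset +
#'   30 percent of the phase width), so the activation leads the
#'   kinematic events it drives.
#' @param burst_gains muscles x 4 matrix of burst amplitudes (>= 0).
#' @param burst_width_scale burst support width as a multiple of the
#'   phase duration; values above 1 let activation bleed into the
#'   neighbouring phases, as real envelopes do.
#' @param emd_ms electromechanical lead of the activation envelope over the
#'   angle trace, in milliseconds.
#' @param noise_band_hz two-element band (Hz) of the raw-EMG carrier noise.
#' @param fs_emg,fs_fsr,fs_angle sampling rates in Hz of the sEMG,
#'   foot-switch and joint-angle streams.
#' @param angle_keys joint-angle keyframes (degrees) at the four phase
#'   onsets. The defaults sketch an ankle dorsi/plantarflexion cycle:
#'   neutral at heel strike, foot flat slightly plantarflexed, peak
#'   dorsiflexion at heel off, peak plantarflexion at toe off.
#' @param angle_keys_mid keyframes (degrees) at the middle of each phase,
#'   giving the profile its fast events: the heel-strike foot-slap dip
#'   within IC and the rapid push-off plantarflexion in late HO.
#' @param cycle_amp_cv stride-to-stride variability: coefficient of
#'   variation of the per-cycle, per-phase amplitude factors that scale
#'   both the activation bursts and the angle excursions they drive. This
#'   shared modulation is what makes the EMG envelope genuinely predictive
#'   of the upcoming angle beyond the angle's own history.
#' @param timing_jitter_ms standard deviation (ms) of per-cycle, per-phase
#'   timing offsets applied identically to the activation bursts and the
#'   angle keyframes they drive (clamped at 2.25 sd). Because the bursts
#'   lead the kinematics by the electromechanical delay, the EMG announces
#'   each timing shift before it appears in the angle trace.
#' @param angle_noise_sd standard deviation (degrees) of smoothed
#'   measurement noise added to the angle trace.
#' @param fsr_noise_sd additive Gaussian noise on the foot-switch plateaus,
#'   as a fraction of plateau height.
#' @param seed integer random seed; fixes every stochastic element.
#' @param condition_shift optional [condition_shift()] describing how an
#'   exoskeleton perturbs gains, burst timing and phase durations.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 60,
                       cycle_mean_s = 1.1,
                       cycle_jitter_cv = 0.05,
                       phase_fractions = c(IC = 0.10, FF = 0.35,
                                           HO = 0.30, TO = 0.25),
                       n_muscles = 9,
                       muscles = DEFAULT_MUSCLES[seq_len(n_muscles)],
                       burst_centers = NULL,
                       burst_gains = default_burst_gains(muscles),
                       burst_width_scale = 1,
                       emd_ms = 40,
                       noise_band_hz = c(20, 450),
                       fs_emg = 1111.11, fs_fsr = 500, fs_angle = 100,
                       angle_keys = c(IC = 0, FF = -3, HO = 10, TO = -18),
                       angle_keys_mid = c(IC = -6, FF = 4, HO = 5,
                                          TO = -4),
                       cycle_amp_cv = 0.35,
                       timing_jitter_ms = 30,
                       angle_noise_sd = 0.3,
                       fsr_noise_sd = 0.05,
                       seed = 1L,
                       condition_shift = NULL) {
  stopifnot(length(phase_fractions) == 4L)
  if (abs(sum(phase_fractions) - 1) > 1e-9)
    stop("phase_fractions must sum to 1")
  if (any(phase_fractions <= 0)) stop("phase_fractions must be positive")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (cycle_mean_s <= 0) stop("cycle_mean_s must be positive")
  if (any(c(fs_emg, fs_fsr, fs_angle) <= 0)) stop("sampling rates must be > 0")
  names(phase_fractions) <- PHASES
  if (is.null(burst_centers)) {
    cum <- cumsum(c(0, phase_fractions))[1:4]
    mid <- cum + 0.3 * phase_fractions
    burst_centers <- matrix(mid, length(muscles), 4, byrow = TRUE,
                            dimnames = list(muscles, PHASES))
  }
  burst_gains <- as.matrix(burst_gains)
  if (any(burst_gains < 0)) stop("burst_gains must be >= 0")
  stopifnot(nrow(burst_gains) == length(muscles),
            ncol(burst_gains) == 4L,
            nrow(burst_centers) == length(muscles))
  cfg <- list(duration_s = duration_s, cycle_mean_s = cycle_mean_s,
              cycle_jitter_cv = cycle_jitter_cv,
              phase_fractions = phase_fractions,
              muscles = muscles, burst_centers = burst_centers,
              burst_gains = burst_gains,
              burst_width_scale = burst_width_scale, emd_ms = emd_ms,
              noise_band_hz = noise_band_hz,
              fs_emg = fs_emg, fs_fsr = fs_fsr, fs_angle = fs_angle,
              angle_keys = angle_keys, angle_keys_mid = angle_keys_mid,
              cycle_amp_cv = cycle_amp_cv,
              timing_jitter_ms = timing_jitter_ms,
              angle_noise_sd = angle_noise_sd,
              fsr_noise_sd = fsr_noise_sd,
              seed = as.integer(seed), condition_shift = condition_shift)
  class(cfg) <- "sim_config"
  cfg
}

#' Exoskeleton condition shift
#'
#' Describes how assisted walking perturbs the generator: per-muscle gain
#' multipliers, a burst-timing delay, and per-phase duration rescaling.
#' The default mimics powered plantarflexion assistance: the assisted
#' plantarflexors (SL, GM, GL) drop to 60 percent of their unassisted
#' drive, bursts arrive 40 ms later (one window increment — a systematic
#' recruitment-timing change, clearly outside the stride-to-stride
#' timing jitter), and initial-contact duration shrinks by 20 percent.
#'
#' @param gain named numeric vector of per-muscle amplitude multipliers.
#' @param burst_delay_ms delay added to every burst centre, in ms.
#' @param phase_scale named multipliers on the four phase fractions
#'   (renormalised to sum to 1).
#' @return an object of class `condition_shift`.
#' @export
condition_shift <- function(gain = NULL, burst_delay_ms = 0,
                            phase_scale = NULL) {
  out <- list(gain = gain, burst_delay_ms = burst_delay_ms,
              phase_scale = phase_scale)
  class(out) <- "condition_shift"
  out
}

#' @rdname condition_shift
#' @export
default_exo_shift <- function() {
  condition_shift(gain = c(SL = 0.6, GM = 0.6, GL = 0.6),
                  burst_delay_ms = 40,
                  phase_scale = c(IC = 0.8, FF = 1, HO = 1, TO = 1))
}

# Apply a condition_shift to a config, returning the perturbed config.
apply_shift <- function(config, shift) {
  if (is.null(shift)) return(config)
  stopifnot(inherits(shift, "condition_shift"))
  cfg <- config
  if (!is.null(shift$phase_scale)) {
    sc <- rep(1, 4); names(sc) <- PHASES
    sc[names(shift$phase_scale)] <- shift$phase_scale
    f <- cfg$phase_fractions * sc
    cfg$phase_fractions <- f / sum(f)
  }
  if (!is.null(shift$gain)) {
    g <- intersect(names(shift$gain), rownames(cfg$burst_gains))
    cfg$burst_gains[g, ] <- cfg$burst_gains[g, ] * shift$gain[g]
  }
  cfg$burst_delay_ms <- shift$burst_delay_ms
  cfg$condition_shift <- shift
  cfg
}

# Quasi-periodic cycle schedule: start times and durations covering
# [0, duration_s]. Durations are truncated-normal around the mean.
draw_cycles <- function(duration_s, mean_s, cv) {
  n_guess <- ceiling(duration_s / mean_s) + 10L
  repeat {
    d <- rnorm(n_guess, mean_s, cv * mean_s)
    d <- pmax(d, 0.4 * mean_s)
    if (sum(d) >= duration_s + mean_s) break
    n_guess <- n_guess * 2L
  }
  starts <- cumsum(c(0, d))
  keep <- starts < duration_s + mean_s
  list(starts = starts[keep], durations = d[seq_len(sum(keep) - 1)])
}

# Map times to (cycle index, within-cycle fraction).
cycle_position <- function(t, starts) {
  idx <- findInterval(t, starts)
  idx[idx < 1L] <- 1L
  idx[idx >= length(starts)] <- length(starts) - 1L
  dur <- starts[idx + 1L] - starts[idx]
  frac <- (t - starts[idx]) / dur
  frac <- pmin(pmax(frac, 0), 1 - 1e-12)
  list(cycle = idx, frac = frac, dur = dur)
}

phase_of_fraction <- function(frac, phase_fractions) {
  bounds <- cumsum(phase_fractions)
  p <- 1L + (frac >= bounds[1]) + (frac >= bounds[2]) + (frac >= bounds[3])
  factor(PHASES[p], levels = PHASES)
}

# Unit raised-cosine burst evaluated at within-cycle fractions. The burst
# has compact support of width w (fraction of cycle), so its per-cycle
# area is w / 2 in fraction units.
burst_shape <- function(frac, center, width) {
  d <- frac - center
  d <- d - round(d)  # circular distance in [-0.5, 0.5)
  out <- numeric(length(frac))
  inside <- abs(d) < width / 2
  out[inside] <- 0.5 * (1 + cos(2 * pi * d[inside] / width))
  out
}

band_limited_noise <- function(n, band_hz, fs) {
  x <- rnorm(n)
  nyq <- fs / 2
  lo <- max(band_hz[1] / nyq, 1e-4)
  hi <- min(band_hz[2] / nyq, 0.99)
  bf <- signal::butter(4, c(lo, hi), type = "pass")
  y <- signal::filter(bf, x)
  y <- as.numeric(y)
  y / stats::sd(y)
}

#' Generate a synthetic walking trial
#'
#' Produces one multi-rate recording with the statistical structure the
#' decoder assumes: a quasi-periodic four-phase gait schedule; per-muscle
#' activation envelopes built from phase-locked raised-cosine bursts that
#' lead the joint angle by the electromechanical delay; raw sEMG as the
#' envelope modulating band-limited zero-mean noise; foot-switch plateaus
#' consistent with the phase schedule; and a smooth periodic angle trace.
#'
#' @param config a [sim_config()].
#' @return an object of class `emg_trial` with elements `emg`
#'   (muscles x samples), `envelope` (the generating truth envelope),
#'   `fsr_heel`, `fsr_toe`, `angle`, `phase_truth` (factor on the FSR
#'   clock), `cycle_starts_s`, `channel_names`, `condition`, `rates`,
#'   `duration_s` and `meta`.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- apply_shift(config, config$condition_shift)
  condition <- if (is.null(config$condition_shift)) "noExo" else "exo"
  set.seed(cfg$seed)

  n_emg <- floor(cfg$duration_s * cfg$fs_emg)
  n_fsr <- floor(cfg$duration_s * cfg$fs_fsr)
  n_ang <- floor(cfg$duration_s * cfg$fs_angle)
  t_emg <- (seq_len(n_emg) - 1) / cfg$fs_emg
  t_fsr <- (seq_len(n_fsr) - 1) / cfg$fs_fsr
  t_ang <- (seq_len(n_ang) - 1) / cfg$fs_angle

  cyc <- draw_cycles(cfg$duration_s, cfg$cycle_mean_s, cfg$cycle_jitter_cv)

  # phase truth on the FSR clock (mechanical events, no EMD)
  pos_fsr <- cycle_position(t_fsr, cyc$starts)
  phase_truth <- phase_of_fraction(pos_fsr$frac, cfg$phase_fractions)

  # FSR plateaus: heel contact during IC+FF, forefoot contact during FF+HO
  heel <- as.numeric(phase_truth %in% c("IC", "FF"))
  toe  <- as.numeric(phase_truth %in% c("FF", "HO"))
  heel <- heel + rnorm(n_fsr, 0, cfg$fsr_noise_sd)
  toe  <- toe + rnorm(n_fsr, 0, cfg$fsr_noise_sd)

  # stride-to-stride amplitude variability, shared (through the
  # electromechanical lead) between the activation bursts and the angle
  # excursions they drive
  n_cyc_tot <- length(cyc$starts)
  amp <- matrix(pmax(1 + rnorm(n_cyc_tot * 4, 0, cfg$cycle_amp_cv), 0.2),
                n_cyc_tot, 4)
  tau_sd <- cfg$timing_jitter_ms / 1000
  tau <- matrix(rnorm(n_cyc_tot * 4, 0, tau_sd), n_cyc_tot, 4)
  tau <- pmin(pmax(tau, -2.25 * tau_sd), 2.25 * tau_sd)

  # envelopes lead the mechanical schedule by emd_ms (and lag by any
  # exoskeleton-induced burst delay)
  lead_s <- cfg$emd_ms / 1000 - if (is.null(cfg$burst_delay_ms)) 0 else
    cfg$burst_delay_ms / 1000
  pos_env <- cycle_position(t_emg + lead_s, cyc$starts)
  ws <- if (is.null(cfg$burst_width_scale)) 1 else cfg$burst_width_scale
  widths <- as.numeric(cfg$phase_fractions) * ws
  n_mus <- length(cfg$muscles)
  envelope <- matrix(0, n_mus, n_emg,
                     dimnames = list(cfg$muscles, NULL))
  emg <- envelope
  for (m in seq_len(n_mus)) {
    env <- numeric(n_emg)
    for (p in 1:4) {
      if (cfg$burst_gains[m, p] <= 0) next
      frac_adj <- pos_env$frac - tau[pos_env$cycle, p] / pos_env$dur
      shape <- burst_shape(frac_adj, cfg$burst_centers[m, p], widths[p])
      env <- env + cfg$burst_gains[m, p] * amp[pos_env$cycle, p] * shape
    }
    carrier <- band_limited_noise(n_emg, cfg$noise_band_hz, cfg$fs_emg)
    sensor <- 0.01 * max(cfg$burst_gains) *
      band_limited_noise(n_emg, cfg$noise_band_hz, cfg$fs_emg)
    envelope[m, ] <- env
    emg[m, ] <- env * carrier + sensor
  }

  # angle trace as a causal response: per-cycle keyframes (scaled and
  # time-jittered together with the bursts that drive them) define a
  # stepwise drive (zero-order hold), smoothed by a causal two-stage
  # exponential filter into S-shaped transitions. Causality matters: the
  # trace must not bend toward a keyframe before the (EMG-announced)
  # drive reaches it, otherwise the angle's own history would already
  # contain what only the leading EMG should know. The filter group
  # delay (2 * tau_smooth) is compensated by advancing the keyframe
  # times so the response stays locked to the mechanical phase schedule.
  cum <- cumsum(c(0, cfg$phase_fractions))[1:4]
  knot_fr <- c(cum, cum + as.numeric(cfg$phase_fractions) / 2)
  knot_ph <- rep(1:4, 2)
  knot_val <- c(as.numeric(cfg$angle_keys), as.numeric(cfg$angle_keys_mid))
  tau_smooth <- 0.02
  n_cycles <- length(cyc$durations)
  kt <- kv <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    kt[[k]] <- cyc$starts[k] + knot_fr * cyc$durations[k] +
      tau[k, knot_ph] - 2 * tau_smooth
    kv[[k]] <- knot_val * amp[k, knot_ph]
  }
  kt <- unlist(kt); kv <- unlist(kv)
  ord <- order(kt)
  drive <- stats::approx(kt[ord], kv[ord], xout = t_ang, rule = 2,
                         method = "constant", f = 0)$y
  a_sm <- exp(-1 / (cfg$fs_angle * tau_smooth))
  angle <- as.numeric(stats::filter(drive * (1 - a_sm), a_sm,
                                    method = "recursive"))
  angle <- as.numeric(stats::filter(angle * (1 - a_sm), a_sm,
                                    method = "recursive"))
  ang_noise <- rnorm(n_ang, 0, cfg$angle_noise_sd)
  ang_noise <- as.numeric(stats::filter(ang_noise, rep(1 / 5, 5), sides = 2))
  ang_noise[is.na(ang_noise)] <- 0
  angle <- angle + ang_noise

  trial <- list(emg = emg, envelope = envelope,
                fsr_heel = heel, fsr_toe = toe,
                angle = angle, phase_truth = phase_truth,
                cycle_starts_s = cyc$starts,
                channel_names = cfg$muscles,
                condition = condition,
                rates = list(fs_emg = cfg$fs_emg, fs_fsr = cfg$fs_fsr,
                             fs_angle = cfg$fs_angle),
                duration_s = cfg$duration_s,
                meta = list(seed = cfg$seed,
                            phase_fractions = cfg$phase_fractions,
                            cycle_mean_s = cfg$cycle_mean_s,
                            emd_ms = cfg$emd_ms))
  class(trial) <- "emg_trial"
  trial
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("<emg_trial> %s, %.1f s, %d EMG channels @ %.2f Hz\n",
              x$condition, x$duration_s, nrow(x$emg), x$rates$fs_emg))
  cat(sprintf("  FSR @ %g Hz (%d samples), angle @ %g Hz (%d samples)\n",
              x$rates$fs_fsr, length(x$fsr_heel),
              x$rates$fs_angle, length(x$angle)))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Label gait phases from foot-switch traces
#'
#' Thresholds the heel and forefoot pressure traces and maps the two binary
#' contact states to the four gait phases: heel only = IC, both = FF,
#' forefoot only = HO, neither = TO. Runs shorter than `min_run_ms` are
#' treated as sensor glitches and merged into a neighbouring run. Cycle
#' boundaries are the TO-to-IC transitions.
#'
#' @param heel,toe equal-length pressure traces.
#' @param fs sampling rate of the traces in Hz.
#' @param threshold contact threshold as a fraction of each trace's maximum,
#'   in (0, 1).
#' @param min_run_ms minimum credible run length in ms; shorter runs are
#'   merged into the longer neighbour.
#' @return a list with `phase` (factor over IC/FF/HO/TO per sample) and
#'   `cycle_starts` (sample indices of TO-to-IC transitions).
#' @export
label_phases_from_fsr <- function(heel, toe, fs, threshold = 0.5,
                                  min_run_ms = 20) {
  stopifnot(length(heel) == length(toe))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  if (max(heel) <= 0 && max(toe) <= 0) stop("no contacts detected")
  h_on <- heel > threshold * max(heel)
  t_on <- toe > threshold * max(toe)
  if (!any(h_on) && !any(t_on)) stop("no contacts detected")
  code <- ifelse(h_on & !t_on, 1L,
          ifelse(h_on & t_on, 2L,
          ifelse(!h_on & t_on, 3L, 4L)))
  min_run <- round(min_run_ms * fs / 1000)
  if (min_run > 1) code <- merge_short_runs(code, min_run)
  phase <- factor(PHASES[code], levels = PHASES)
  cycle_starts <- which(code == 1L & c(0L, head(code, -1)) == 4L)
  list(phase = phase, cycle_starts = cycle_starts)
}

# Merge runs shorter than min_run into the longer neighbouring run.
merge_short_runs <- function(code, min_run) {
  repeat {
    r <- rle(code)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_run)
    if (length(short) == 0L) break
    i <- short[which.min(r$lengths[short])]
    left  <- if (i > 1L) r$lengths[i - 1L] else -1L
    right <- if (i < length(r$lengths)) r$lengths[i + 1L] else -1L
    r$values[i] <- if (left >= right) r$values[i - 1L] else r$values[i + 1L]
    code <- inverse.rle(r)
  }
  code
}

#' Generate a matched unassisted/assisted trial pair
#'
#' Builds two trials sharing the muscle set and joint-profile family: one
#' under the unassisted (`noExo`) generator, one with the supplied condition
#' shift applied (`exo`). With a zero shift the two trials are generated
#' from identical parameters.
#'
#' @param config a [sim_config()] (its own `condition_shift` is ignored).
#' @param shift a [condition_shift()].
#' @param exo_duration_s optional different duration for the assisted trial.
#' @return list with elements `noExo` and `exo`, both `emg_trial`s.
#' @export
make_condition_pair <- function(config, shift = default_exo_shift(),
                                exo_duration_s = NULL) {
  cfg0 <- config
  cfg0$condition_shift <- NULL
  cfg1 <- config
  cfg1$condition_shift <- shift
  if (!is.null(exo_duration_s)) cfg1$duration_s <- exo_duration_s
  list(noExo = generate_trial(cfg0), exo = generate_trial(cfg1))
}
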