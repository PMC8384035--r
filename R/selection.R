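#' Per-phase activation areas
#'
#' Integrates a muscle-activation trace over each gait-phase segment of each
#' complete cycle (trapezoidal rule) and averages the per-phase areas across
#' cycles. A complete cycle runs from one TO-to-IC transition to the next.
#'
#' @param a activation samples.
#' @param phase factor over IC/FF/HO/TO, one label per sample of `a`.
#' @param fs sampling rate of `a` (Hz).
#' @return named list with `areas` (named numeric over the four phases, in
#'   activation-seconds) and `n_cycles`.
#' @export
phase_areas <- function(a, phase, fs) {
  stopifnot(length(a) == length(phase))
  code <- as.integer(factor(phase, levels = PHASES))
  starts <- which(code == 1L & c(0L, head(code, -1)) == 4L)
  if (length(starts) < 2L) stop("no complete cycle in the trace")
  acc <- matrix(0, length(starts) - 1L, 4L)
  for (k in seq_len(length(starts) - 1L)) {
    idx <- starts[k]:(starts[k + 1L] - 1L)
    for (p in 1:4) {
      sel <- idx[code[idx] == p]
      if (length(sel) == 0L) next
      # trapezoid over each contiguous run, extended one sample to the
      # right so the integral reaches the onset of the next segment
      runs <- split(sel, cumsum(c(1L, diff(sel) != 1L)))
      for (r in runs) {
        j <- c(r, min(r[length(r)] + 1L, length(a)))
        acc[k, p] <- acc[k, p] +
          sum((a[j[-length(j)]] + a[j[-1]]) / 2) / fs
      }
    }
  }
  areas <- colMeans(acc)
  names(areas) <- PHASES
  list(areas = areas, n_cycles = nrow(acc))
}

#' Build the muscle-effect matrix
#'
#' Normalises each muscle's per-phase activation areas by that muscle's own
#' maximum area, yielding unitless effects in `[0, 1]` whose row maximum is
#' exactly 1.
#'
#' @param areas muscles x 4 matrix of per-phase areas (named rows), or the
#'   output list of [phase_areas()] stacked with `rbind`.
#' @param n_cycles number of cycles the areas were averaged over (recorded).
#' @return object of class `effect_matrix`: list with `muscles`, `areas`,
#'   `effects`, `phases`, `n_cycles_averaged`.
#' @export
effect_matrix <- function(areas, n_cycles = NA_integer_) {
  areas <- as.matrix(areas)
  stopifnot(ncol(areas) == 4L, all(areas >= 0))
  if (is.null(colnames(areas))) colnames(areas) <- PHASES
  row_max <- apply(areas, 1, max)
  zero <- row_max == 0
  if (any(zero))
    stop("all-zero activation areas for muscle(s): ",
         paste(rownames(areas)[zero], collapse = ", "))
  effects <- areas / row_max
  out <- list(muscles = rownames(areas), areas = areas, effects = effects,
              phases = PHASES, n_cycles_averaged = n_cycles)
  class(out) <- "effect_matrix"
  out
}

#' Effect matrix straight from a trial
#'
#' Runs the full activation chain on every channel, aligns the phase truth
#' to the EMG clock, and assembles the effect matrix.
#'
#' @param trial an `emg_trial`.
#' @param params an [activation_params()].
#' @return an `effect_matrix`.
#' @export
trial_effect_matrix <- function(trial, params = activation_params()) {
  aligned <- align_trial(trial)
  act <- activation_traces(trial, params)
  areas <- t(vapply(seq_len(nrow(act$a)), function(m) {
    phase_areas(act$a[m, ], aligned$phase, act$fs)$areas
  }, numeric(4)))
  rownames(areas) <- trial$channel_names
  n_cyc <- phase_areas(act$a[1, ], aligned$phase, act$fs)$n_cycles
  effect_matrix(areas, n_cycles = n_cyc)
}

#' Select an informative muscle subset
#'
#' Implements the effect-based sensor-reduction rule. A muscle is
#' *discarded* when at least three of its four phase effects have a
#' within-`delta` partner among the other phases of the same muscle, i.e.
#' its activation profile is too flat to discriminate phases. After
#' discarding, a *coverage repair* pass checks every phase: if the best
#' retained effect in a phase falls below `min_phase_cover`, the discarded
#' muscle with the highest effect in that phase is re-added (ties broken by
#' input order), so at least the four phase-dominant muscles survive.
#'
#' @param E an `effect_matrix` (or a muscles x 4 numeric matrix of effects).
#' @param delta similarity threshold on effect differences, in (0, 1).
#' @param min_phase_cover minimum acceptable best retained effect per phase.
#' @return list with `retained` (character), `discarded` (character) and
#'   `report` (data.frame with per-muscle partnered-phase counts and
#'   decisions).
#' @export
select_muscles <- function(E, delta = 0.15, min_phase_cover = 0.6) {
  if (inherits(E, "effect_matrix")) E <- E$effects
  E <- as.matrix(E)
  stopifnot(ncol(E) == 4L)
  if (delta <= 0 || delta >= 1) stop("delta must be in (0,1)")
  if (is.null(rownames(E))) rownames(E) <- paste0("m", seq_len(nrow(E)))
  muscles <- rownames(E)

  partnered <- vapply(seq_len(nrow(E)), function(m) {
    row <- E[m, ]
    sum(vapply(1:4, function(p) {
      # small tolerance so boundary cases are not decided by FP noise
      any(abs(row[p] - row[-p]) <= delta + 1e-9)
    }, logical(1)))
  }, integer(1))
  discard <- partnered >= 3L

  readded <- rep(FALSE, nrow(E))
  for (p in 1:4) {
    kept <- which(!discard | readded)
    best_kept <- if (length(kept)) max(E[kept, p]) else -Inf
    if (best_kept < min_phase_cover) {
      cand <- which(discard & !readded)
      if (length(cand)) {
        readded[cand[which.max(E[cand, p])]] <- TRUE
      }
    }
  }
  keep <- !discard | readded
  if (!any(keep)) stop("empty retained set after coverage repair")
  report <- data.frame(
    muscle = muscles,
    partnered_phases = partnered,
    discarded_by_rule = discard,
    readded_for_coverage = readded,
    retained = keep,
    row.names = NULL)
  list(retained = muscles[keep], discarded = muscles[!keep],
       report = report)
}

#' Reference nine-muscle effect table
#'
#' Loads the bundled effect table for nine lower-limb muscles across the
#' four gait phases, measured during level treadmill walking. Used as the
#' worked example for the muscle-selection rule.
#'
#' @return a 9 x 4 numeric matrix (muscles x phases).
#' @export
reference_effect_table <- function() {
  path <- system.file("extdata", "nine_muscle_effects.csv",
                      package = "gaitdecode", mustWork = TRUE)
  df <- utils::read.csv(path)
  m <- as.matrix(df[, PHASES])
  rownames(m) <- df$muscle
  m
}
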