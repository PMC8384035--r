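#' Save a trial to disk
#'
#' Two layouts are supported. `"container"` is a single-file RDS container
#' that round-trips bit-exactly. `"csv-dir"` is a directory of plain CSV
#' streams (`emg.csv`, `fsr.csv`, `angle.csv`, `envelope.csv`) with the
#' first column holding time in seconds, plus a `meta.json` carrying the
#' sampling rates, channel names, condition and seed.
#'
#' @param trial an `emg_trial`.
#' @param path file (container) or directory (csv-dir) to write.
#' @param format `"container"` or `"csv-dir"`.
#' @return `path`, invisibly.
#' @export
save_trial <- function(trial, path, format = c("container", "csv-dir")) {
  format <- match.arg(format)
  stopifnot(inherits(trial, "emg_trial"))
  if (format == "container") {
    saveRDS(trial, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  t_emg <- (seq_len(ncol(trial$emg)) - 1) / trial$rates$fs_emg
  emg_df <- data.frame(time = t_emg, t(trial$emg), check.names = FALSE)
  utils::write.csv(emg_df, file.path(path, "emg.csv"), row.names = FALSE)
  env_df <- data.frame(time = t_emg, t(trial$envelope), check.names = FALSE)
  utils::write.csv(env_df, file.path(path, "envelope.csv"), row.names = FALSE)
  t_fsr <- (seq_along(trial$fsr_heel) - 1) / trial$rates$fs_fsr
  fsr_df <- data.frame(time = t_fsr, heel = trial$fsr_heel,
                       toe = trial$fsr_toe,
                       phase = as.character(trial$phase_truth))
  utils::write.csv(fsr_df, file.path(path, "fsr.csv"), row.names = FALSE)
  t_ang <- (seq_along(trial$angle) - 1) / trial$rates$fs_angle
  ang_df <- data.frame(time = t_ang, angle = trial$angle)
  utils::write.csv(ang_df, file.path(path, "angle.csv"), row.names = FALSE)
  meta <- list(rates = trial$rates, channel_names = trial$channel_names,
               condition = trial$condition, duration_s = trial$duration_s,
               cycle_starts_s = trial$cycle_starts_s, meta = trial$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trial from disk
#'
#' @param path file or directory written by [save_trial()].
#' @param format `"container"` or `"csv-dir"`.
#' @return an `emg_trial`.
#' @export
load_trial <- function(path, format = c("container", "csv-dir")) {
  format <- match.arg(format)
  if (format == "container") {
    if (!file.exists(path)) stop("file not found: ", path)
    trial <- readRDS(path)
    stopifnot(inherits(trial, "emg_trial"))
    return(trial)
  }
  need <- c("emg", "fsr", "angle")
  for (s in need) {
    if (!file.exists(file.path(path, paste0(s, ".csv"))))
      stop(sprintf("stream '%s' not found", s))
  }
  if (!file.exists(file.path(path, "meta.json")))
    stop("rate attributes absent: meta.json not found")
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$rates)) stop("rate attributes absent in meta.json")
  emg_df <- utils::read.csv(file.path(path, "emg.csv"), check.names = FALSE)
  emg <- t(as.matrix(emg_df[, -1, drop = FALSE]))
  env_path <- file.path(path, "envelope.csv")
  envelope <- if (file.exists(env_path)) {
    env_df <- utils::read.csv(env_path, check.names = FALSE)
    t(as.matrix(env_df[, -1, drop = FALSE]))
  } else matrix(NA_real_, nrow(emg), ncol(emg))
  fsr_df <- utils::read.csv(file.path(path, "fsr.csv"))
  ang_df <- utils::read.csv(file.path(path, "angle.csv"))
  trial <- list(emg = emg, envelope = envelope,
                fsr_heel = fsr_df$heel, fsr_toe = fsr_df$toe,
                angle = ang_df$angle,
                phase_truth = factor(fsr_df$phase, levels = PHASES),
                cycle_starts_s = meta$cycle_starts_s,
                channel_names = meta$channel_names,
                condition = meta$condition,
                rates = as.list(meta$rates),
                duration_s = meta$duration_s,
                meta = as.list(meta$meta))
  rownames(emg) <- meta$channel_names
  trial$emg <- emg
  class(trial) <- "emg_trial"
  trial
}

#' Synchronise the multi-rate streams of a trial
#'
#' Puts the three acquisition clocks on a common time origin: every EMG
#' sample receives the phase label of the nearest foot-switch sample
#' (nearest-neighbour, because phase is categorical), and the angle trace
#' becomes a query function `angle_fun(t)` by linear interpolation, clamped
#' at both ends. Re-aligning an aligned trial is a no-op.
#'
#' @param trial an `emg_trial` (or an already-aligned trial).
#' @return an object of class `aligned_trial`: the original trial plus
#'   `phase` (factor, one label per EMG sample), `angle_fun`, and `t_emg`.
#' @export
align_trial <- function(trial) {
  if (inherits(trial, "aligned_trial")) return(trial)
  stopifnot(inherits(trial, "emg_trial"))
  if (length(trial$phase_truth) == 0L) stop("empty phase labels")
  if (ncol(trial$emg) == 0L || length(trial$angle) == 0L)
    stop("streams must be nonempty")
  t_emg <- (seq_len(ncol(trial$emg)) - 1) / trial$rates$fs_emg
  idx_fsr <- round(t_emg * trial$rates$fs_fsr) + 1
  idx_fsr <- pmin(pmax(idx_fsr, 1L), length(trial$phase_truth))
  phase <- trial$phase_truth[idx_fsr]
  t_ang <- (seq_along(trial$angle) - 1) / trial$rates$fs_angle
  angle_fun <- stats::approxfun(t_ang, trial$angle, method = "linear",
                                rule = 2)
  out <- trial
  out$phase <- phase
  out$angle_fun <- angle_fun
  out$t_emg <- t_emg
  class(out) <- c("aligned_trial", "emg_trial")
  out
}
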