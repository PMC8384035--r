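#' Sliding-window specification
#'
#' Converts the window length and increment from milliseconds to samples
#' (rounded to the nearest sample) at a given rate.
#'
#' @param length_ms window length (ms); default 180.
#' @param increment_ms window increment (ms); default 40.
#' @param fs sampling rate (Hz).
#' @return object of class `window_spec` with `length_samples` and
#'   `increment_samples`.
#' @export
window_spec <- function(length_ms = 180, increment_ms = 40, fs = 1111.11) {
  length_samples <- round(length_ms * fs / 1000)
  increment_samples <- round(increment_ms * fs / 1000)
  if (!(length_samples > increment_samples && increment_samples > 0))
    stop("window length must exceed the increment and both must be positive")
  out <- list(length_ms = length_ms, increment_ms = increment_ms, fs = fs,
              length_samples = length_samples,
              increment_samples = increment_samples)
  class(out) <- "window_spec"
  out
}

#' Number of sliding windows in a stream
#'
#' `floor((n_samples - length) / increment) + 1`, or 0 (with a warning)
#' when the stream is shorter than one window.
#'
#' @param n_samples stream length in samples.
#' @param spec a [window_spec()].
#' @return integer window count.
#' @export
window_count <- function(n_samples, spec) {
  if (n_samples < spec$length_samples) {
    warning("stream shorter than one window")
    return(0L)
  }
  as.integer((n_samples - spec$length_samples) %/% spec$increment_samples + 1L)
}

#' Time-domain features of one EMG segment
#'
#' The four standard myoelectric window features: mean absolute value
#' (MAV), zero crossings (ZC), slope sign changes (SSC) and waveform
#' length (WL). The ZC and SSC counts admit amplitude thresholds to reject
#' noise-floor crossings.
#'
#' @param x segment samples (length >= 3).
#' @param zc_threshold minimum amplitude step for a counted zero crossing.
#' @param ssc_threshold minimum neighbouring step for a counted slope
#'   change.
#' @return named numeric vector `c(mav, zc, ssc, wl)`.
#' @export
td_features <- function(x, zc_threshold = 0, ssc_threshold = 0) {
  n <- length(x)
  if (n < 3L) stop("segment must have at least 3 samples")
  stopifnot(zc_threshold >= 0, ssc_threshold >= 0)
  d <- diff(x)
  mav <- mean(abs(x))
  zc <- sum(x[-n] * x[-1] < 0 & abs(d) >= zc_threshold)
  xm <- x[2:(n - 1)]
  dl <- xm - x[1:(n - 2)]
  dr <- xm - x[3:n]
  ssc <- sum(dl * dr > 0 & (abs(dl) >= ssc_threshold | abs(dr) >= ssc_threshold))
  wl <- sum(abs(d))
  c(mav = mav, zc = zc, ssc = ssc, wl = wl)
}

#' Build the windowed feature frame of a trial
#'
#' Segments the (band-passed) multi-channel sEMG with a continuous sliding
#' window and computes the four time-domain features per channel, giving a
#' feature vector of dimension `4 n` per window. Each window also carries
#' its majority phase label, the joint angle at the window end, and the
#' angle `horizon_ms` ahead (the regression target); windows whose future
#' time falls beyond the trial are dropped.
#'
#' @param aligned an `aligned_trial` (see [align_trial()]); a raw
#'   `emg_trial` is aligned automatically.
#' @param channels channel subset to use; default all.
#' @param spec a [window_spec()] at the trial's EMG rate.
#' @param horizon_ms prediction horizon for `angle_future` (ms).
#' @param zc_threshold,ssc_threshold feature thresholds, see
#'   [td_features()].
#' @param bandpass apply a 20-450 Hz band-pass (with mains notch) to the
#'   raw sEMG before feature extraction.
#' @return object of class `feature_frame`: list with `times` (window end
#'   times, s), `X` (windows x 4n matrix, columns `mav_<ch>`, `zc_<ch>`,
#'   `ssc_<ch>`, `wl_<ch>` grouped by channel), `phase`, `angle_now`,
#'   `angle_future`, `channels`, `spec`, `horizon_ms`.
#' @export
build_feature_frame <- function(aligned, channels = NULL,
                                spec = NULL, horizon_ms = 40,
                                zc_threshold = 0, ssc_threshold = 0,
                                bandpass = TRUE) {
  aligned <- align_trial(aligned)
  fs <- aligned$rates$fs_emg
  if (is.null(spec)) spec <- window_spec(fs = fs)
  if (is.null(channels)) channels <- aligned$channel_names
  unknown <- setdiff(channels, aligned$channel_names)
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  emg <- aligned$emg[channels, , drop = FALSE]
  if (bandpass) {
    nyq <- fs / 2
    bp <- signal::butter(4, pmin(c(20, 450) / nyq, 0.99), type = "pass")
    nt <- signal::butter(2, c(48, 52) / nyq, type = "stop")
    for (m in seq_len(nrow(emg)))
      emg[m, ] <- signal::filtfilt(nt, signal::filtfilt(bp, emg[m, ]))
  }
  n <- ncol(emg)
  n_win <- window_count(n, spec)
  if (n_win == 0L) stop("trial too short for one window")
  L <- spec$length_samples; I <- spec$increment_samples
  starts <- (seq_len(n_win) - 1L) * I + 1L
  ends <- starts + L - 1L
  t_end <- (ends - 1) / fs
  duration <- aligned$duration_s
  horizon_s <- horizon_ms / 1000
  keep <- t_end + horizon_s <= duration
  n_keep <- sum(keep)
  if (n_keep == 0L) stop("horizon drops every window")

  X <- matrix(0, n_keep, 4L * length(channels))
  colnames(X) <- as.vector(vapply(channels, function(ch)
    paste0(c("mav_", "zc_", "ssc_", "wl_"), ch), character(4)))
  phase <- character(n_keep)
  kept <- which(keep)
  for (j in seq_along(kept)) {
    w <- kept[j]
    idx <- starts[w]:ends[w]
    for (m in seq_along(channels)) {
      X[j, (4 * (m - 1) + 1):(4 * m)] <-
        td_features(emg[m, idx], zc_threshold, ssc_threshold)
    }
    tab <- table(aligned$phase[idx])
    phase[j] <- names(tab)[which.max(tab)]
  }
  times <- t_end[kept]
  out <- list(times = times,
              X = X,
              phase = factor(phase, levels = PHASES),
              angle_now = aligned$angle_fun(times),
              angle_future = aligned$angle_fun(times + horizon_s),
              channels = channels, spec = spec, horizon_ms = horizon_ms,
              condition = aligned$condition)
  class(out) <- "feature_frame"
  out
}

#' @export
print.feature_frame <- function(x, ...) {
  cat(sprintf("<feature_frame> %d windows x %d features (%d channels)\n",
              nrow(x$X), ncol(x$X), length(x$channels)))
  cat("  phases:", paste(sprintf("%s=%d", levels(x$phase),
                                 tabulate(x$phase, 4)), collapse = " "), "\n")
  invisible(x)
}

#' Subset a feature frame by window index
#'
#' Keeps the selected windows of a frame (all per-window fields move
#' together); chiefly used for time-ordered train/test splits and
#' minute-budget slicing.
#'
#' @param frame a `feature_frame`.
#' @param idx window indices to keep.
#' @return a `feature_frame` with the selected windows.
#' @export
subset_frame <- function(frame, idx) {
  out <- frame
  out$times <- frame$times[idx]
  out$X <- frame$X[idx, , drop = FALSE]
  out$phase <- frame$phase[idx]
  out$angle_now <- frame$angle_now[idx]
  out$angle_future <- frame$angle_future[idx]
  out
}
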