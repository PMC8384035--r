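#' Activation-dynamics parameters
#'
#' Parameters of the EMG-to-activation chain: the preprocessing filters, the
#' second-order recursive neural-activation filter and the nonlinear
#' activation map. The recursion is parameterised through its poles
#' `gamma1`, `gamma2` (both must lie strictly inside the unit circle for
#' stability), from which `beta1 = gamma1 + gamma2`,
#' `beta2 = gamma1 * gamma2`, and the gain `alpha = 1 + beta1 + beta2` so
#' the filter has unit DC gain.
#'
#' @param gamma1,gamma2 filter poles, each in (-1, 1).
#' @param d_ms electromechanical delay of the filter, in ms.
#' @param A nonlinear shape factor in `[-3, 0]`; -3 is strongly
#'   exponential, 0 the linear limit. Default -2.
#' @param lowpass_hz envelope low-pass cutoff (Hz).
#' @param bandpass_hz raw-EMG band-pass corners (Hz).
#' @param notch_hz mains notch frequency (Hz).
#' @return an object of class `activation_params`.
#' @export
activation_params <- function(gamma1 = -0.5, gamma2 = -0.5, d_ms = 40,
                              A = -2, lowpass_hz = 4,
                              bandpass_hz = c(20, 450), notch_hz = 50) {
  if (abs(gamma1) >= 1 || abs(gamma2) >= 1)
    stop("unstable recursion: |gamma1| and |gamma2| must be < 1")
  if (A < -3 || A > 0) stop("A must lie in [-3, 0]")
  beta1 <- gamma1 + gamma2
  beta2 <- gamma1 * gamma2
  alpha <- 1 + beta1 + beta2
  out <- list(alpha = alpha, beta1 = beta1, beta2 = beta2,
              gamma1 = gamma1, gamma2 = gamma2, d_ms = d_ms, A = A,
              lowpass_hz = lowpass_hz, bandpass_hz = bandpass_hz,
              notch_hz = notch_hz)
  class(out) <- "activation_params"
  out
}

#' Preprocess one raw sEMG channel into an envelope
#'
#' Band-pass and notch filtering, full-wave rectification, normalisation by
#' the peak rectified value, and a zero-phase low-pass, yielding an
#' amplitude envelope in approximately `[0, 1]` (small filter overshoot is
#' clipped at zero from below).
#'
#' @param x raw sEMG samples.
#' @param fs sampling rate (Hz).
#' @param params an [activation_params()].
#' @return numeric envelope, same length as `x`.
#' @export
preprocess_emg <- function(x, fs, params = activation_params()) {
  stopifnot(length(x) > 0, all(is.finite(x)))
  nyq <- fs / 2
  bp <- signal::butter(4, pmin(params$bandpass_hz / nyq, 0.99), type = "pass")
  y <- signal::filtfilt(bp, x)
  if (!is.null(params$notch_hz) && params$notch_hz < nyq) {
    nt <- signal::butter(2, c(params$notch_hz - 2, params$notch_hz + 2) / nyq,
                         type = "stop")
    y <- signal::filtfilt(nt, y)
  }
  y <- abs(y)
  peak <- max(y)
  if (peak == 0) stop("peak is zero")
  y <- y / peak
  lp <- signal::butter(4, params$lowpass_hz / nyq, type = "low")
  env <- signal::filtfilt(lp, y)
  pmax(env, 0)
}

#' Neural activation: the recursive second-order filter
#'
#' Computes `u(i) = alpha * e(i - d) - beta1 * u(i-1) - beta2 * u(i-2)`
#' with zero initial conditions and `e(k) = 0` for `k < 0`. Under the
#' construction constraints of [activation_params()] the filter is stable
#' with unit DC gain, so a constant envelope `e = c` drives `u` to `c`.
#'
#' @param e envelope samples.
#' @param fs sampling rate of `e` (Hz); the delay `d_ms` is rounded to the
#'   nearest whole sample.
#' @param params an [activation_params()].
#' @return numeric vector `u`, same length as `e`.
#' @export
neural_activation <- function(e, fs, params = activation_params()) {
  stopifnot(all(is.finite(e)))
  d <- round(params$d_ms * fs / 1000)
  ed <- if (d > 0) c(rep(0, d), head(e, length(e) - d)) else e
  u <- stats::filter(params$alpha * ed,
                     filter = c(-params$beta1, -params$beta2),
                     method = "recursive")
  as.numeric(u)
}

#' Muscle activation: the nonlinear activation map
#'
#' Maps neural activation to mechanical muscle activation through
#' `a = (exp(A u) - 1) / (exp(A) - 1)`. The map is strictly increasing with
#' `a(0) = 0` and `a(1) = 1`; at `A = 0` the analytic limit `a = u` is used.
#'
#' @param u neural activation samples.
#' @param A nonlinear shape factor in `[-3, 0]`.
#' @return numeric vector `a`, same length as `u`.
#' @export
muscle_activation <- function(u, A = -2) {
  stopifnot(all(is.finite(u)))
  if (A > 0 || A < -3) stop("A must lie in [-3, 0]")
  if (A == 0) return(u)
  (exp(A * u) - 1) / (exp(A) - 1)
}

#' Full EMG-to-activation chain for a trial
#'
#' Convenience wrapper: per channel, preprocess to an envelope, run the
#' recursive neural-activation filter, and apply the nonlinear map.
#'
#' @param trial an `emg_trial`.
#' @param params an [activation_params()].
#' @return list with `envelope`, `u` and `a` (muscles x samples matrices)
#'   and `fs`.
#' @export
activation_traces <- function(trial, params = activation_params()) {
  stopifnot(inherits(trial, "emg_trial"))
  fs <- trial$rates$fs_emg
  env <- t(apply(trial$emg, 1, preprocess_emg, fs = fs, params = params))
  u <- t(apply(env, 1, neural_activation, fs = fs, params = params))
  a <- muscle_activation(u, params$A)
  dimnames(env) <- dimnames(u) <- dimnames(a) <-
    list(trial$channel_names, NULL)
  list(envelope = env, u = u, a = a, fs = fs)
}

#' Fit the recursion parameters against a reference trace
#'
#' Bounded search over the filter poles and the delay minimising the mean
#' squared error between the produced activation `a(t)` and a reference
#' trace. A coarse grid over `(gamma1, gamma2, d)` seeds a Nelder-Mead
#' refinement constrained to the stability region; the result never fits
#' worse than the default parameters.
#'
#' @param e envelope samples.
#' @param reference reference activation trace, same length as `e`.
#' @param fs sampling rate (Hz).
#' @param A nonlinear shape factor (held fixed).
#' @param d_grid_ms candidate delays (ms) for the coarse stage.
#' @return an [activation_params()] with attribute `"mse"`.
#' @export
fit_activation_params <- function(e, reference, fs, A = -2,
                                  d_grid_ms = seq(0, 80, by = 10)) {
  stopifnot(length(e) == length(reference))
  if (stats::sd(reference) == 0) {
    warning("degenerate constant reference; returning defaults")
    p <- activation_params(A = A)
    attr(p, "mse") <- mse_of(p, e, reference, fs)
    return(p)
  }
  obj <- function(g1, g2, d_ms) {
    if (abs(g1) >= 0.999 || abs(g2) >= 0.999) return(Inf)
    p <- activation_params(gamma1 = g1, gamma2 = g2, d_ms = d_ms, A = A)
    mse_of(p, e, reference, fs)
  }
  grid <- expand.grid(g1 = seq(-0.8, 0.8, by = 0.2),
                      g2 = seq(-0.8, 0.8, by = 0.2),
                      d = d_grid_ms)
  vals <- mapply(obj, grid$g1, grid$g2, grid$d)
  best <- grid[which.min(vals), ]
  # refine poles at the best few delays
  d_near <- unique(pmax(0, best$d + c(-5, 0, 5)))
  cand <- list()
  for (d in d_near) {
    o <- stats::optim(c(best$g1, best$g2),
                      function(th) obj(th[1], th[2], d),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
    cand[[length(cand) + 1L]] <- list(par = o$par, d = d, value = o$value)
  }
  vbest <- cand[[which.min(vapply(cand, `[[`, 0, "value"))]]
  default <- activation_params(A = A)
  mse_default <- mse_of(default, e, reference, fs)
  if (vbest$value <= mse_default) {
    p <- activation_params(gamma1 = vbest$par[1], gamma2 = vbest$par[2],
                           d_ms = vbest$d, A = A)
    attr(p, "mse") <- vbest$value
  } else {
    p <- default
    attr(p, "mse") <- mse_default
  }
  p
}

mse_of <- function(params, e, reference, fs) {
  a <- muscle_activation(neural_activation(e, fs, params), params$A)
  mean((a - reference)^2)
}
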