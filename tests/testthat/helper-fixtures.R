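# Small shared fixtures. Trials are generated in code at test time; the
# short ones here keep the deterministic module tests fast.

short_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_trial(sim_config(duration_s = 20, seed = 101))
    cache
  }
})

selected_channels <- c("RF", "TA", "ST", "GM", "GL")

# Literal-definition brute-force oracle for the four time-domain features.
td_features_oracle <- function(x, zc_thr = 0, ssc_thr = 0) {
  n <- length(x)
  mav <- sum(abs(x)) / n
  zc <- 0
  for (k in 1:(n - 1)) {
    if (x[k] * x[k + 1] < 0 && abs(x[k] - x[k + 1]) >= zc_thr) zc <- zc + 1
  }
  ssc <- 0
  for (k in 2:(n - 1)) {
    dl <- x[k] - x[k - 1]
    dr <- x[k] - x[k + 1]
    if (dl * dr > 0 && (abs(dl) >= ssc_thr || abs(dr) >= ssc_thr))
      ssc <- ssc + 1
  }
  wl <- 0
  for (k in 1:(n - 1)) wl <- wl + abs(x[k + 1] - x[k])
  c(mav = mav, zc = zc, ssc = ssc, wl = wl)
}

# Phase label sequence with exact per-phase sample counts, preceded by a
# short TO run so the first TO->IC transition opens a cycle.
make_label_cycle <- function(counts, n_cycles = 1, lead_to = 10,
                             trail_ic = 5) {
  one <- rep(PHASES_TEST, times = counts)
  factor(c(rep("TO", lead_to), rep(one, n_cycles), rep("IC", trail_ic)),
         levels = PHASES_TEST)
}

PHASES_TEST <- c("IC", "FF", "HO", "TO")
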