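# Shared fixture builders. Everything is generated in code; no binary
# fixtures.

# RR series with the given intervals (ms), starting at t = 0.
rr_from_intervals <- function(intervals, flags = NULL) {
  rr_series(c(0, cumsum(intervals) / 1000), intervals, flags)
}

# Uniform HR curve carrying hr(t) sampled at fs.
make_hr <- function(hr_fun, duration, fs = 4) {
  t <- seq(0, duration, by = 1 / fs)
  hr_curve(t, hr_fun(t), fs)
}

# Synthetic ECG: Gaussian R-wave impulse train at the given beat times.
make_ecg <- function(beat_times, fs = 250, duration = NULL) {
  if (is.null(duration)) duration <- max(beat_times) + 0.5
  t <- seq(0, duration, by = 1 / fs)
  x <- numeric(length(t))
  for (bt in beat_times) x <- x + exp(-((t - bt) / 0.01)^2)
  ecg_record(x, fs)
}

# A stepped simulated session and its evaluated trials, memoised per
# profile arguments to keep the suite fast.
eval_stepped <- function(rf_true, seed, sigma_rr = 0, a_bg = 20, ...) {
  prof <- subject_profile(rf_true = rf_true, sigma_rr = sigma_rr,
                          a_bg = a_bg, seed = seed, ...)
  ses <- simulate_session(prof, build_stepped_protocol())
  suppressWarnings(evaluate_trials(session_trials(ses)))
}

# Trials data.frame from explicit metric values (freqs descending or not).
trials_df <- function(freq, mean_amp, lf_ratio, plv) {
  df <- data.frame(freq = freq, mean_amp = mean_amp,
                   lf_ratio = lf_ratio, plv = plv)
  class(df) <- c("frequency_trials", "data.frame")
  df
}

# Brute-force two-sided exact Wilcoxon signed-rank p over all 2^n sign
# assignments (independent oracle for paired_wilcoxon).
wilcoxon_brute <- function(x, y, alternative = "two.sided") {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}
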