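#' Simulated-subject profile
#'
#' Ground truth for the cardiorespiratory simulator. Respiratory sinus
#' arrhythmia is modulated by a second-order resonator centred at the
#' subject's true resonance frequency: paced breathing near `rf_true`
#' produces the largest heart-rate oscillations.
#'
#' @param rf_true True resonance frequency (breaths/min), in `[4.0, 8.0]`.
#' @param rr0 Baseline RR interval (ms), in `[600, 1200]`.
#' @param a_rsa RSA interval-modulation amplitude at unit gain (ms).
#' @param zeta Resonator damping ratio, in (0, 1).
#' @param a_hf Amplitude of the unpaced high-frequency RR modulation (ms).
#' @param f_hf Frequency of that modulation (Hz), default 0.25.
#' @param a_bg RMS amplitude (ms) of the background low-frequency RR
#'   variability (Mayer-wave / intrinsic baroreflex activity in
#   0.04-0.17 Hz, random phase under the seed). This structural
#'   variability competes with paced RSA, so phase synchrony and the
#'   coherence ratio genuinely peak near resonance rather than saturating.
#' @param sigma_rr Additive white RR noise SD (ms).
#' @param seed Integer seed governing the subject's noise realisation.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(rf_true, rr0 = 800, a_rsa = 20, zeta = 0.1,
                            a_hf = 10, f_hf = 0.25, a_bg = 20,
                            sigma_rr = 5, seed = 1L) {
  if (rf_true < 4.0 || rf_true > 8.0)
    stop("rf_true must lie in [4.0, 8.0] breaths/min")
  if (rr0 < 600 || rr0 > 1200) stop("rr0 must lie in [600, 1200] ms")
  if (zeta <= 0 || zeta >= 1) stop("zeta must lie in (0, 1)")
  if (a_rsa < 0 || a_hf < 0 || a_bg < 0 || sigma_rr < 0)
    stop("amplitudes and noise SD must be non-negative")
  structure(list(rf_true = rf_true, rr0 = rr0, a_rsa = a_rsa, zeta = zeta,
                 a_hf = a_hf, f_hf = f_hf, a_bg = a_bg,
                 sigma_rr = sigma_rr, seed = as.integer(seed)),
            class = "subject_profile")
}

#' Second-order resonance gain and phase
#'
#' With `r = f / rf_true`:
#' `gain = 1 / sqrt((1 - r^2)^2 + (2 zeta r)^2)` and
#' `phase = -atan2(2 zeta r, 1 - r^2)`. At `f = rf_true` the gain is
#' `1/(2 zeta)` and the phase is `-pi/2`.
#'
#' @param f Breathing frequency (breaths/min), > 0; vectorised.
#' @param profile A [subject_profile()].
#' @return A list with `gain` (dimensionless) and `phase` (radians).
#' @export
resonance_gain <- function(f, profile) {
  if (any(f <= 0)) stop("f must be positive")
  r <- f / profile$rf_true
  z <- profile$zeta
  list(gain = 1 / sqrt((1 - r^2)^2 + (2 * z * r)^2),
       phase = -atan2(2 * z * r, 1 - r^2))
}

# Run fn with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_private_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate a paced-breathing session
#'
#' Respiration phase follows the pacer waveform. The continuous RR
#' process is
#' `RR(t) = rr0 + a_rsa * gain(f(t)) * sin(phase_resp(t) + phase(f(t)) + pi)
#'  + a_hf * sin(2 pi f_hf t) + bg(t) + sigma_rr * w(t)`
#' with `w` standard white noise drawn per beat and `bg` the subject's
#' background low-frequency variability (a seeded random-phase sinusoid
#' bank in 0.04-0.17 Hz with RMS `a_bg`), both under the profile seed.
#' Beats are generated by forward stepping,
#' `t_(k+1) = t_k + RR(t_k)/1000`, and intervals are clipped to
#' `[300, 2000]` ms (a clipped session carries `clipped = TRUE`).
#'
#' @param profile A [subject_profile()].
#' @param protocol A [pacer_protocol()].
#' @param fs_trace Sampling rate of the stored respiration trace (Hz).
#' @return An object of class `sim_session`: `rr` ([rr_series()]), `resp`
#'   (list `t`, `phase`, `freq`), `protocol`, `truth`, `clipped`.
#' @export
simulate_session <- function(profile, protocol, fs_trace = 8) {
  wf <- pacer_waveform(protocol, fs_trace)
  dur <- protocol_duration(protocol)
  worst <- profile$a_rsa / (2 * profile$zeta) + profile$a_hf +
    3 * profile$a_bg + 4 * profile$sigma_rr
  if (profile$rr0 - worst <= 0)
    stop("profile parameters can produce non-positive RR intervals")
  phase_at <- stats::approxfun(wf$t, wf$phase, rule = 2)
  freq_at <- stats::approxfun(wf$t, wf$freq, rule = 2)
  clipped <- FALSE
  rr <- with_private_seed(profile$seed, function() {
    nbank <- 48L
    bg_f <- stats::runif(nbank, 0.04, 0.17)
    bg_ph <- stats::runif(nbank, 0, 2 * pi)
    bg_scale <- profile$a_bg * sqrt(2 / nbank)
    bt <- numeric(ceiling(dur / 0.3) + 2)
    bt[1] <- 0
    k <- 1L
    while (bt[k] < dur) {
      t <- bt[k]
      f <- freq_at(t)
      g <- resonance_gain(f, profile)
      rr_t <- profile$rr0 +
        profile$a_rsa * g$gain * sin(phase_at(t) + g$phase + pi) +
        profile$a_hf * sin(2 * pi * profile$f_hf * t) +
        bg_scale * sum(sin(2 * pi * bg_f * t + bg_ph)) +
        profile$sigma_rr * stats::rnorm(1)
      if (rr_t < 300 || rr_t > 2000) {
        clipped <<- TRUE
        rr_t <- min(max(rr_t, 300), 2000)
      }
      bt[k + 1] <- t + rr_t / 1000
      k <- k + 1L
    }
    rr_series(bt[1:k])
  })
  if (clipped) warning("some simulated intervals were clipped to [300, 2000] ms")
  structure(list(rr = rr, resp = wf, protocol = protocol, truth = profile,
                 clipped = clipped),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat("<sim_session> ", x$protocol$kind, " protocol, ",
      length(x$rr$intervals), " beats over ",
      round(protocol_duration(x$protocol)), " s (true RF ",
      x$truth$rf_true, " BPM)\n", sep = "")
  invisible(x)
}

#' Split a stepped simulated session into per-frequency trials
#'
#' The first `settle_s` seconds of each step are excluded: immediately
#' after a frequency change the heart-rate oscillation is still
#' re-entraining to the new pacing rate, and the transition transient
#' would contaminate both the spectral and the per-breath metrics
#' (standard practice in stepped resonance assessment).
#'
#' @param session A [simulate_session()] result under a stepped protocol.
#' @param settle_s Settle-in exclusion at each step start (s), default 20.
#' @return A list, one element per protocol step, each with `freq`
#'   (breaths/min), `rr` (the step's [rr_series()], times re-zeroed to the
#'   analysed span start), and `resp` (`t`, `phase` on that span, same
#'   origin).
#' @export
session_trials <- function(session, settle_s = 20) {
  stopifnot(inherits(session, "sim_session"),
            session$protocol$kind == "stepped")
  grid <- session$protocol$grid
  sd_ <- session$protocol$step_duration
  lapply(seq_along(grid), function(i) {
    a <- (i - 1) * sd_ + settle_s; b <- i * sd_
    sel <- session$rr$beat_times >= a & session$rr$beat_times < b
    bt <- session$rr$beat_times[sel]
    rs <- session$resp$t >= a & session$resp$t <= b
    list(freq = grid[i],
         rr = if (sum(sel) >= 2) rr_series(bt - a) else NULL,
         resp = list(t = session$resp$t[rs] - a,
                     phase = session$resp$phase[rs]))
  })
}

#' Extract a per-breath annotated sweep from a sliding session
#'
#' @param session A [simulate_session()] result under a sliding protocol.
#' @return A list of class `breath_sweep`: `rr`, `cycle_starts` (s) and
#'   `cycle_freqs` (breaths/min, 60 / cycle duration).
#' @export
session_sweep <- function(session) {
  stopifnot(inherits(session, "sim_session"),
            session$protocol$kind == "sliding")
  starts <- breath_cycle_starts(session$protocol)
  durs <- diff(starts)
  structure(list(rr = session$rr,
                 cycle_starts = starts[-length(starts)],
                 cycle_freqs = 60 / durs),
            class = "breath_sweep")
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from `master_seed`;
#' `rf_true` is drawn uniformly from `rf_range`, other profile fields from
#' the supplied ranges (point ranges give identical values).
#'
#' @param n Number of subjects.
#' @param master_seed Integer master seed.
#' @param rf_range True-RF range (breaths/min), default `c(4.5, 6.5)`.
#' @param rr0_range,a_rsa_range,zeta_range,sigma_range Profile field
#'   ranges.
#' @return A list of [subject_profile()] objects of length `n`.
#' @export
simulate_cohort <- function(n, master_seed = 1L,
                            rf_range = c(4.5, 6.5),
                            rr0_range = c(700, 950),
                            a_rsa_range = c(15, 25),
                            zeta_range = c(0.08, 0.15),
                            sigma_range = c(3, 8)) {
  stopifnot(n >= 1)
  with_private_seed(master_seed, function() {
    draws <- function(rg) stats::runif(n, rg[1], rg[2])
    rf <- draws(rf_range); rr0 <- draws(rr0_range)
    ar <- draws(a_rsa_range); zt <- draws(zeta_range)
    sg <- draws(sigma_range)
    seeds <- (as.integer(master_seed) %% 1000003L) * 1000L + seq_len(n)
    lapply(seq_len(n), function(i)
      subject_profile(rf_true = rf[i], rr0 = rr0[i], a_rsa = ar[i],
                      zeta = zt[i], sigma_rr = sg[i], seed = seeds[i]))
  })
}
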