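#' Time-domain HRV metrics
#'
#' SDNN (sample SD of RR intervals, ms), RMSSD (root-mean-square of
#' successive differences, ms) and pNN50 (percentage of successive
#' differences strictly greater than 50 ms). Artifact-flagged intervals
#' are excluded.
#'
#' @param rr An [rr_series()]; at least 2 usable intervals for SDNN,
#'   3 for RMSSD/pNN50.
#' @return A list of class `hrv_time_domain` with `sdnn`, `rmssd`, `pnn50`.
#' @examples
#' rr <- rr_series(c(0, 0.8, 1.61, 2.4, 3.205))
#' time_domain_metrics(rr)
#' @export
time_domain_metrics <- function(rr) {
  iv <- rr$intervals[rr$flags != "artifact"]
  if (length(iv) < 2) stop("SDNN needs at least 2 intervals")
  if (length(iv) < 3) stop("RMSSD/pNN50 need at least 3 intervals")
  d <- diff(iv)
  structure(list(sdnn = stats::sd(iv),
                 rmssd = sqrt(mean(d^2)),
                 pnn50 = 100 * mean(abs(d) > 50)),
            class = "hrv_time_domain")
}

#' @export
print.hrv_time_domain <- function(x, ...) {
  cat(sprintf("SDNN %.2f ms | RMSSD %.2f ms | pNN50 %.1f %%\n",
              x$sdnn, x$rmssd, x$pnn50))
  invisible(x)
}

#' Spectral HRV metrics (LF/HF decomposition)
#'
#' Welch power spectral density of the mean-removed RR tachogram derived
#' from an evenly sampled heart-rate curve (RR in ms, via 60000/HR).
#' Defaults: 120 s Hann segments, 50% overlap, linear detrend per segment.
#' Band powers are trapezoidal integrals over the half-open low-frequency
#' (0.04-0.15 Hz) and high-frequency (0.15-0.40 Hz) bands, and the
#' coherence ratio is LF/(LF+HF).
#'
#' @param hr An [hr_curve()] covering at least 120 s for the default
#'   estimator. Curves shorter than two segments fall back to a
#'   single-segment periodogram with a warning.
#' @param segment_s Welch segment length in seconds (default 120).
#' @return A list of class `spectral_result` with `freqs`, `psd` (ms^2/Hz),
#'   `lf_power`, `hf_power` (ms^2) and `lf_ratio`.
#' @export
spectral_metrics <- function(hr, segment_s = 120) {
  dur <- hr$t[length(hr$t)] - hr$t[1]
  if (dur < segment_s)
    stop("curve duration ", round(dur), " s is below the ", segment_s,
         " s minimum for the spectral estimator")
  rr_ms <- 60000 / hr$hr
  x <- rr_ms - mean(rr_ms)
  nperseg <- round(segment_s * hr$fs_out)
  if (length(x) < 1.25 * nperseg) {
    # a second segment overlapping > 75% adds nothing: use one segment
    warning("fewer than 2 Welch segments available; ",
            "falling back to a single-segment periodogram")
    nperseg <- length(x)
  }
  w <- welch_psd(x, fs = hr$fs_out, nperseg = nperseg)
  lf <- band_power(w$freqs, w$psd, 0.04, 0.15)
  hf <- band_power(w$freqs, w$psd, 0.15, 0.40)
  ratio <- if (lf + hf > 0) lf / (lf + hf) else NA_real_
  structure(list(freqs = w$freqs, psd = w$psd,
                 lf_power = lf, hf_power = hf, lf_ratio = ratio),
            class = "spectral_result")
}

#' Per-breath peak-to-trough heart-rate amplitudes
#'
#' For each breath cycle window `[start_k, start_(k+1))` the amplitude is
#' max(HR) - min(HR) over the window (the HRmax-HRmin metric of
#' respiratory sinus arrhythmia).
#'
#' @param hr An [hr_curve()].
#' @param cycle_bounds Breath-cycle start times (s); the last bound closes
#'   the final cycle. At least one complete cycle must lie within the
#'   curve span.
#' @return A list of class `breath_amplitudes` with `per_cycle`
#'   (beats/min, one per complete cycle) and `mean_amp`.
#' @export
breath_amplitudes <- function(hr, cycle_bounds) {
  if (length(cycle_bounds) < 2) stop("need at least 2 cycle bounds")
  cycle_bounds <- sort(cycle_bounds)
  t0 <- hr$t[1]; t1 <- hr$t[length(hr$t)]
  amps <- numeric(0)
  for (k in seq_len(length(cycle_bounds) - 1)) {
    a <- cycle_bounds[k]; b <- cycle_bounds[k + 1]
    if (a < t0 - 1e-9 || b > t1 + 1e-9) next
    idx <- which(hr$t >= a & hr$t < b)
    if (length(idx) < 2) next
    amps <- c(amps, max(hr$hr[idx]) - min(hr$hr[idx]))
  }
  if (!length(amps)) stop("no complete breath cycle within the curve span")
  structure(list(per_cycle = amps, mean_amp = mean(amps)),
            class = "breath_amplitudes")
}

#' Cardiorespiratory phase synchrony (phase-locking value)
#'
#' Band-passes the cardiac oscillation around the pacing frequency
#' (zero-phase 4th-order Butterworth, pacing +- 0.03 Hz), extracts the
#' instantaneous phase by Hilbert transform, and computes the
#' phase-locking value of the phase difference against respiration:
#' `plv = |mean(exp(i * (phi_HR - phi_resp)))|`.
#'
#' The filtering and phase extraction are performed on the RR tachogram
#' implied by the curve (`60000/hr`): RR is the physiologically linear
#' substrate, so this avoids the harmonic artefacts the reciprocal RR->HR
#' map injects at large oscillation amplitudes. In the small-oscillation
#' limit the two phases differ by exactly pi, which is removed so the
#' reported lag is heart-rate-referenced.
#'
#' @param hr An [hr_curve()].
#' @param resp_phase Respiration phase (radians) on the same time grid.
#' @param pacing_freq Pacing frequency in Hz, within `[0.05, 0.17]`.
#' @return A list of class `phase_synchrony` with `plv` in `[0, 1]` and
#'   `mean_phase_lag` in `(-pi, pi]` (radians).
#' @export
phase_synchrony <- function(hr, resp_phase, pacing_freq) {
  if (length(resp_phase) != length(hr$hr))
    stop("resp_phase must share the heart-rate curve's time grid")
  if (pacing_freq < 0.05 || pacing_freq > 0.17)
    stop("pacing_freq must lie in [0.05, 0.17] Hz")
  lo <- max(pacing_freq - 0.03, 0.005)
  hi <- min(pacing_freq + 0.03, hr$fs_out / 2 * 0.99)
  ba <- butter_bandpass(2, lo, hi, hr$fs_out)   # order-4 bandpass
  rr_ms <- 60000 / hr$hr
  xb <- filtfilt_bw(ba$b, ba$a, rr_ms - mean(rr_ms))
  phi_hr <- Arg(analytic_signal(xb)) + pi       # RR and HR are antiphase
  dphi <- phi_hr - resp_phase
  # discard filter/Hilbert edge transients (1.5 pacing cycles per side)
  n <- length(dphi)
  trim <- min(floor((n - 8) / 2), ceiling(1.5 / pacing_freq * hr$fs_out))
  if (trim > 0) dphi <- dphi[(trim + 1):(n - trim)]
  v <- mean(exp(1i * dphi))
  structure(list(plv = Mod(v), mean_phase_lag = Arg(v)),
            class = "phase_synchrony")
}

#' Pre/during/post training-effect report
#'
#' Time-domain metrics per training phase, plus the during/pre ratio per
#' metric. Ratios with a zero pre-training denominator are reported as
#' `NA` (missing).
#'
#' @param pre,during,post [rr_series()] objects, each spanning at least
#'   60 s.
#' @return A list of class `training_report`: `phases` (named list of
#'   [time_domain_metrics()] results) and `ratios` (during/pre per metric).
#' @export
training_effect_report <- function(pre, during, post) {
  phases <- list(pre = pre, during = during, post = post)
  for (nm in names(phases)) {
    span <- diff(range(phases[[nm]]$beat_times))
    if (span < 60)
      stop("phase '", nm, "' spans only ", round(span), " s (< 60 s)")
  }
  td <- lapply(phases, time_domain_metrics)
  ratio1 <- function(d, p) if (p == 0) NA_real_ else d / p
  ratios <- list(sdnn = ratio1(td$during$sdnn, td$pre$sdnn),
                 rmssd = ratio1(td$during$rmssd, td$pre$rmssd),
                 pnn50 = ratio1(td$during$pnn50, td$pre$pnn50))
  structure(list(phases = td, ratios = ratios), class = "training_report")
}
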