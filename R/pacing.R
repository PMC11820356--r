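#' Paced-breathing protocols
#'
#' A pacer protocol is either `stepped` (a descending grid of breathing
#' frequencies, each held for a fixed duration), `sliding` (a continuous
#' sweep from a start to an end frequency) or `fixed` (one frequency).
#'
#' @param kind One of `"stepped"`, `"sliding"`, `"fixed"`.
#' @param grid Frequency grid in breaths/min (stepped/fixed).
#' @param step_duration Seconds per step (stepped) or total duration
#'   (fixed).
#' @param sweep_from,sweep_to Sweep endpoints in breaths/min (sliding).
#' @param sweep_duration Total sweep duration in seconds (sliding).
#' @param inhale_fraction Fraction of each cycle spent inhaling, in (0, 1);
#'   default 0.4 (inhale shorter than exhale). Used only for waveform
#'   shaping.
#' @return An object of class `pacer_protocol`.
#' @export
pacer_protocol <- function(kind = c("stepped", "sliding", "fixed"),
                           grid = NULL, step_duration = NULL,
                           sweep_from = NULL, sweep_to = NULL,
                           sweep_duration = NULL,
                           inhale_fraction = 0.4) {
  kind <- match.arg(kind)
  if (inhale_fraction <= 0 || inhale_fraction >= 1)
    stop("inhale_fraction must be in (0, 1)")
  chk <- function(f) {
    if (any(f < 4.0 | f > 8.5))
      stop("breathing frequencies must lie in [4.0, 8.5] BPM")
  }
  if (kind %in% c("stepped", "fixed")) {
    if (is.null(grid) || is.null(step_duration))
      stop("stepped/fixed protocols need grid and step_duration")
    chk(grid)
    if (step_duration <= 0) stop("step_duration must be positive")
  } else {
    if (is.null(sweep_from) || is.null(sweep_to) || is.null(sweep_duration))
      stop("sliding protocols need sweep_from, sweep_to, sweep_duration")
    chk(c(sweep_from, sweep_to))
    if (sweep_duration <= 0) stop("sweep_duration must be positive")
  }
  structure(list(kind = kind, grid = grid, step_duration = step_duration,
                 sweep_from = sweep_from, sweep_to = sweep_to,
                 sweep_duration = sweep_duration,
                 inhale_fraction = inhale_fraction),
            class = "pacer_protocol")
}

#' Build the standard stepped assessment protocol
#'
#' Default grid descends from 8 to 4.5 breaths/min in 0.5 BPM steps, each
#' held for 180 s (8 steps, 1440 s total). When `grid_lo` is not reachable
#' from `grid_hi` in multiples of `step`, the grid ends at the last
#' reachable frequency with a warning.
#'
#' @param grid_hi,grid_lo Highest and lowest frequency (breaths/min).
#' @param step Grid decrement (breaths/min).
#' @param step_duration Seconds per step.
#' @return A `stepped` [pacer_protocol()].
#' @export
build_stepped_protocol <- function(grid_hi = 8.0, grid_lo = 4.5,
                                   step = 0.5, step_duration = 180) {
  if (grid_hi <= grid_lo) stop("grid_hi must exceed grid_lo")
  if (step <= 0) stop("step must be positive")
  grid <- seq(grid_hi, grid_lo, by = -step)
  if (abs(grid[length(grid)] - grid_lo) > 1e-9)
    warning("grid_lo ", grid_lo, " not reachable from ", grid_hi,
            " in steps of ", step, "; grid ends at ", grid[length(grid)])
  pacer_protocol("stepped", grid = grid, step_duration = step_duration)
}

#' Protocol total duration in seconds
#' @param protocol A [pacer_protocol()].
#' @return Duration (s).
#' @export
protocol_duration <- function(protocol) {
  switch(protocol$kind,
         stepped = length(protocol$grid) * protocol$step_duration,
         fixed = protocol$step_duration,
         sliding = protocol$sweep_duration)
}

#' Target breathing frequency at time t
#' @param protocol A [pacer_protocol()].
#' @param t Time (s) from protocol start.
#' @return Target frequency (breaths/min) at each `t`.
#' @export
target_frequency <- function(protocol, t) {
  dur <- protocol_duration(protocol)
  t <- pmin(pmax(t, 0), dur - 1e-12)
  switch(protocol$kind,
         stepped = protocol$grid[pmin(length(protocol$grid),
                                      1 + floor(t / protocol$step_duration))],
         fixed = rep(protocol$grid[1], length(t)),
         sliding = protocol$sweep_from +
           (protocol$sweep_to - protocol$sweep_from) * t / dur)
}

#' Pacer waveform: respiration phase and target-frequency traces
#'
#' Integrates `dphi/dt = freq(t)/60` cycles per second so the phase is
#' continuous across step boundaries. Phase is returned in radians
#' (non-decreasing, not wrapped).
#'
#' @param protocol A [pacer_protocol()].
#' @param fs Sampling rate of the trace (Hz).
#' @return A list with `t` (s), `phase` (radians), `freq` (breaths/min).
#' @export
pacer_waveform <- function(protocol, fs) {
  if (fs <= 0) stop("fs must be positive")
  dur <- protocol_duration(protocol)
  t <- seq(0, dur, by = 1 / fs)
  f <- target_frequency(protocol, t)
  # trapezoidal phase integration, cycles -> radians
  dphi <- c(0, diff(t) * (f[-1] + f[-length(f)]) / 2 / 60)
  list(t = t, phase = 2 * pi * cumsum(dphi), freq = f)
}

#' Breath-cycle start times under a protocol
#'
#' Times at which the pacer phase crosses integer multiples of one cycle.
#'
#' @param protocol A [pacer_protocol()].
#' @param fs Internal integration rate (Hz), default 50.
#' @return Cycle start times (s), beginning at 0.
#' @export
breath_cycle_starts <- function(protocol, fs = 50) {
  wf <- pacer_waveform(protocol, fs)
  cyc <- wf$phase / (2 * pi)
  n_full <- floor(cyc[length(cyc)])
  if (n_full < 1) return(0)
  # invert the monotone phase for each integer crossing
  starts <- stats::approx(cyc, wf$t, xout = 0:n_full)$y
  starts
}

#' Adaptive pacing adjustment
#'
#' When the last three per-breath heart-rate amplitudes are strictly
#' decreasing, the guiding frequency moves 0.25 breaths/min toward the
#' resting breathing rate (clamped to protocol bounds); otherwise it is
#' unchanged. Callers should apply at most one adjustment per 3 breaths.
#'
#' @param target_freq Current guiding frequency (breaths/min).
#' @param recent_amps Most recent per-breath amplitudes (beats/min),
#'   oldest first; at least 3.
#' @param resting_freq Resting breathing rate (breaths/min), default 12.
#' @param bounds Allowed frequency range, default `c(4.0, 8.5)`.
#' @return The new guiding frequency (breaths/min).
#' @export
adaptive_adjust <- function(target_freq, recent_amps, resting_freq = 12,
                            bounds = c(4.0, 8.5)) {
  if (length(recent_amps) < 3)
    stop("need at least 3 recent amplitudes")
  last3 <- utils::tail(recent_amps, 3)
  if (!(last3[1] > last3[2] && last3[2] > last3[3]))
    return(target_freq)
  dir <- sign(resting_freq - target_freq)
  if (dir == 0) return(target_freq)
  new <- target_freq + dir * 0.25
  clamped <- min(max(new, bounds[1]), bounds[2])
  if (clamped != new)
    warning("adjusted frequency clamped to protocol bounds")
  clamped
}

#' Detect repeated breathing deviations
#'
#' Raises a `frequency_deviation` event when the measured breathing
#' frequency differs from target by more than `freq_tol` on at least
#' `run_length` consecutive breaths, and a `depth_deviation` event when
#' breathing depth falls below `depth_frac` of baseline for at least
#' `run_length` consecutive breaths. One event is raised per qualifying
#' run, timestamped at the run's first qualifying breath.
#'
#' @param breath_times Per-breath onset times (s).
#' @param measured_freq Per-breath measured frequency (breaths/min).
#' @param target_freq Per-breath target frequency (breaths/min).
#' @param depth Per-breath depth (arbitrary units); optional.
#' @param baseline_depth Baseline depth (> 0); required when `depth` given.
#' @param freq_tol Frequency deviation threshold (breaths/min), default 1.0.
#' @param depth_frac Depth threshold as a fraction of baseline, default 0.5.
#' @param run_length Minimum consecutive breaths, default 3.
#' @return A data.frame of alert events (`time`, `type`, `magnitude`,
#'   `detail`), zero rows when no deviation repeats.
#' @export
detect_deviation <- function(breath_times, measured_freq, target_freq,
                             depth = NULL, baseline_depth = NULL,
                             freq_tol = 1.0, depth_frac = 0.5,
                             run_length = 3) {
  n <- length(breath_times)
  stopifnot(length(measured_freq) == n, length(target_freq) == n)
  events <- list()
  emit_runs <- function(bad, type, magnitude) {
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values & r$lengths >= run_length)) {
      i <- starts[j]
      events[[length(events) + 1]] <<- data.frame(
        time = breath_times[i], type = type,
        magnitude = magnitude[i],
        detail = sprintf("%d consecutive breaths", r$lengths[j]),
        stringsAsFactors = FALSE)
    }
  }
  fdev <- abs(measured_freq - target_freq)
  emit_runs(fdev > freq_tol, "frequency_deviation", fdev)
  if (!is.null(depth)) {
    if (is.null(baseline_depth) || baseline_depth <= 0)
      stop("baseline_depth must be positive when depth is supplied")
    stopifnot(length(depth) == n)
    emit_runs(depth < depth_frac * baseline_depth, "depth_deviation",
              depth / baseline_depth)
  }
  if (!length(events))
    return(data.frame(time = numeric(0), type = character(0),
                      magnitude = numeric(0), detail = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, events)
  out[order(out$time), , drop = FALSE]
}

#' Weekly training-adherence check
#'
#' A calendar week (ISO week, Monday start) is compliant when it contains
#' at least `min_sessions` sessions of at least `min_duration` seconds.
#' Non-compliant weeks raise a `session_missed` alert.
#'
#' @param session_log A data.frame with columns `date` (Date or
#'   `"%Y-%m-%d"` strings) and `duration` (s).
#' @param min_sessions Sessions required per week, default 4.
#' @param min_duration Minimum qualifying session length (s), default 900.
#' @return A list with `weeks` (data.frame: `week`, `qualifying`,
#'   `compliant`) and `alerts` (one `session_missed` row per
#'   non-compliant week).
#' @export
adherence_check <- function(session_log, min_sessions = 4,
                            min_duration = 900) {
  if (!nrow(session_log))
    return(list(weeks = data.frame(week = character(0),
                                   qualifying = integer(0),
                                   compliant = logical(0)),
                alerts = data.frame(week = character(0),
                                    type = character(0),
                                    detail = character(0))))
  dates <- as.Date(session_log$date)
  wk <- format(dates, "%G-W%V")
  ok <- session_log$duration >= min_duration
  qual <- tapply(ok, wk, sum)
  weeks <- data.frame(week = names(qual),
                      qualifying = as.integer(qual),
                      compliant = as.integer(qual) >= min_sessions,
                      row.names = NULL, stringsAsFactors = FALSE)
  bad <- weeks[!weeks$compliant, , drop = FALSE]
  alerts <- data.frame(
    week = bad$week, type = rep("session_missed", nrow(bad)),
    detail = sprintf("%d of %d qualifying sessions", bad$qualifying,
                     min_sessions),
    stringsAsFactors = FALSE)
  list(weeks = weeks, alerts = alerts)
}
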