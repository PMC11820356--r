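#' RR-interval series
#'
#' Container for a beat-to-beat RR series: beat times in seconds from
#' session start and the intervals between successive beats in
#' milliseconds, with a per-interval quality flag.
#'
#' @param beat_times Numeric vector of beat times (s), strictly increasing.
#' @param intervals Optional numeric vector of intervals (ms). When omitted
#'   it is derived from `beat_times`; when supplied it must agree with the
#'   successive time differences to within 1 ms.
#' @param flags Character vector of per-interval quality flags, one of
#'   `"ok"`, `"artifact"`, `"interpolated"`. Defaults to all `"ok"`.
#' @return An object of class `rr_series` with elements `beat_times`,
#'   `intervals` and `flags` (`length(intervals) == length(beat_times) - 1`).
#' @examples
#' rr <- rr_series(c(0, 1, 2.01))
#' rr$intervals
#' @export
rr_series <- function(beat_times, intervals = NULL, flags = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2)
    stop("an RR series needs at least 2 beats")
  dt <- diff(beat_times)
  if (any(dt <= 0))
    stop("beat times must be strictly increasing")
  derived <- dt * 1000
  if (is.null(intervals)) {
    intervals <- derived
  } else {
    intervals <- as.numeric(intervals)
    if (length(intervals) != length(beat_times) - 1)
      stop("length(intervals) must equal length(beat_times) - 1")
    if (any(intervals <= 0))
      stop("all intervals must be positive")
    if (any(abs(intervals - derived) > 1))
      stop("intervals disagree with beat-time differences by more than 1 ms")
  }
  if (is.null(flags)) flags <- rep("ok", length(intervals))
  if (!all(flags %in% c("ok", "artifact", "interpolated")))
    stop("flags must be 'ok', 'artifact' or 'interpolated'")
  structure(list(beat_times = beat_times,
                 intervals = intervals,
                 flags = flags),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat("<rr_series> ", length(x$intervals), " intervals, ",
      sprintf("%.1f", diff(range(x$beat_times))), " s span, mean RR ",
      sprintf("%.1f", mean(x$intervals)), " ms, ",
      sum(x$flags != "ok"), " flagged\n", sep = "")
  invisible(x)
}

#' Single-lead ECG record
#'
#' @param samples Numeric amplitude samples (mV).
#' @param fs Sampling rate (Hz), > 0.
#' @param t0 Start time (s), default 0.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, t0 = 0) {
  if (fs <= 0) stop("fs must be positive")
  if (length(samples) < 2) stop("need at least 2 samples")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "ecg_record")
}

#' Evenly sampled instantaneous heart-rate curve
#'
#' @param t Uniform time grid (s).
#' @param hr Heart rate (beats/min), positive.
#' @param fs_out Grid sampling rate (Hz).
#' @return An object of class `hr_curve`.
#' @export
hr_curve <- function(t, hr, fs_out) {
  if (length(t) != length(hr)) stop("t and hr lengths differ")
  if (any(hr <= 0)) stop("hr must be positive everywhere")
  structure(list(t = t, hr = hr, fs_out = fs_out), class = "hr_curve")
}

#' Read an RR-interval series from CSV
#'
#' Expects two columns, `time_s` and `rr_ms` (header optional); lines
#' starting with `#` are metadata comments. Column consistency is enforced
#' to within 1 ms.
#'
#' @param path Path to the CSV file.
#' @return An [rr_series()] with all flags `"ok"`.
#' @export
read_rr_csv <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(trimws(raw), "#") & nzchar(trimws(raw))]
  if (!length(raw)) stop("no data rows in ", path)
  has_header <- grepl("[A-Za-z]", strsplit(raw[1], ",")[[1]][1])
  df <- utils::read.csv(text = raw, header = has_header,
                        col.names = c("time_s", "rr_ms"))
  if (any(is.na(df$time_s)) || any(is.na(df$rr_ms)))
    stop("non-numeric values in RR CSV")
  if (any(df$rr_ms <= 0)) stop("negative or zero RR interval in ", path)
  # file stores one row per beat; rr_ms on the first row is the interval
  # ending at the second beat, the last row's rr_ms may be NA-like 0 or
  # simply repeat; accept both row-per-interval and row-per-beat layouts
  if (nrow(df) < 2) stop("need at least 2 beats")
  rr_series(df$time_s, df$rr_ms[-nrow(df)])
}

#' Write an RR-interval series to CSV
#'
#' One row per beat (`time_s,rr_ms`); the final beat repeats the last
#' interval so the file round-trips through [read_rr_csv()]. `meta` entries
#' are written as `# key=value` comment lines.
#'
#' @param rr An [rr_series()].
#' @param path Output path.
#' @param meta Named character vector of metadata.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(rr, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s=%s", names(meta), meta), con)
  writeLines("time_s,rr_ms", con)
  rrcol <- c(rr$intervals, rr$intervals[length(rr$intervals)])
  writeLines(sprintf("%.6f,%.6f", rr$beat_times, rrcol), con)
  invisible(path)
}

#' Detect R peaks in a single-lead ECG
#'
#' Derivative-energy detector with an adaptive threshold and a 250 ms
#' refractory period (Pan-Tompkins style). The signal is differenced,
#' squared and smoothed with a 150 ms moving window; peaks must exceed an
#' adaptive threshold tracking recent peak heights.
#'
#' @param ecg An [ecg_record()]; `fs` must be at least 100 Hz.
#' @return Strictly increasing beat times (s). A flat signal yields an
#'   empty vector with a warning.
#' @export
detect_r_peaks <- function(ecg) {
  if (ecg$fs < 100) stop("R-peak detection needs fs >= 100 Hz")
  x <- ecg$samples
  if (max(x) - min(x) < 1e-9) {
    warning("flat ECG signal: no R peaks detected")
    return(numeric(0))
  }
  d <- c(0, diff(x)) * ecg$fs
  e <- d^2
  win <- max(1L, round(0.15 * ecg$fs))
  kernel <- rep(1 / win, win)
  sm <- stats::filter(e, kernel, sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  refractory <- round(0.25 * ecg$fs)
  thr <- 0.3 * max(sm)
  peaks <- integer(0)
  i <- 2L
  n <- length(sm)
  while (i < n) {
    if (sm[i] > thr && sm[i] >= sm[i - 1] && sm[i] >= sm[i + 1]) {
      if (!length(peaks) || i - peaks[length(peaks)] >= refractory) {
        peaks <- c(peaks, i)
        thr <- 0.3 * (0.7 * sm[i] + 0.3 * max(sm))   # adapt toward recent peaks
        i <- i + refractory
        next
      }
    }
    i <- i + 1L
  }
  if (!length(peaks)) {
    warning("no R peaks found above threshold")
    return(numeric(0))
  }
  # refine each to the local signal maximum within +-50 ms
  half <- as.integer(round(0.05 * ecg$fs))
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(length(x), p + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  ecg$t0 + (refined - 1) / ecg$fs
}

#' Clean an RR series of artifacts
#'
#' Intervals outside 300-2000 ms, or differing by more than 20% from the
#' previous accepted interval, are marked as artifacts and handled per
#' `policy`: flagged in place, linearly interpolated over beat time, or
#' dropped (beats merged).
#'
#' @param rr An [rr_series()].
#' @param policy One of `"flag"`, `"interpolate"`, `"drop"`.
#' @return A cleaned [rr_series()].
#' @export
clean_rr <- function(rr, policy = c("flag", "interpolate", "drop")) {
  policy <- match.arg(policy)
  iv <- rr$intervals
  n <- length(iv)
  bad <- logical(n)
  last_ok <- NA_real_
  for (k in seq_len(n)) {
    out_abs <- iv[k] < 300 || iv[k] > 2000
    out_rel <- !is.na(last_ok) && abs(iv[k] - last_ok) > 0.2 * last_ok
    bad[k] <- out_abs || out_rel
    if (!bad[k]) last_ok <- iv[k]
  }
  if (mean(bad) > 0.5)
    stop("more than 50% of intervals are artifacts; series unusable")
  flags <- rr$flags
  flags[bad] <- "artifact"
  if (policy == "flag" || !any(bad))
    return(rr_series(rr$beat_times, rr$intervals, flags))
  if (policy == "drop") {
    # remove artifact intervals and compact the series: absolute beat
    # timing after a dropped interval is not preserved
    kept <- rr$intervals[!bad]
    bt <- rr$beat_times[1] + c(0, cumsum(kept) / 1000)
    return(rr_series(bt, kept, rr$flags[!bad]))
  }
  # interpolate: replace bad intervals by linear interpolation of the
  # good intervals against the time of the interval midpoint
  mid <- (rr$beat_times[-1] + rr$beat_times[-(n + 1)]) / 2
  good <- !bad
  if (sum(good) < 2) stop("too few good intervals to interpolate")
  iv[bad] <- stats::approx(mid[good], rr$intervals[good], xout = mid[bad],
                           rule = 2)$y
  flags[bad] <- "interpolated"
  # rebuild beat times from interpolated intervals to keep consistency
  bt <- rr$beat_times[1] + c(0, cumsum(iv) / 1000)
  rr_series(bt, iv, flags)
}

#' Instantaneous heart-rate curve from an RR series
#'
#' Places HR = 60000/RR at each interval midpoint and cubic-interpolates
#' onto a uniform grid clipped to the observed beat span. Artifact-flagged
#' intervals are excluded from the interpolation support.
#'
#' @param rr An [rr_series()] with at least 4 beats.
#' @param fs_out Output sampling rate (Hz), default 4.
#' @return An [hr_curve()].
#' @export
instantaneous_hr <- function(rr, fs_out = 4) {
  if (fs_out <= 0) stop("fs_out must be positive")
  if (length(rr$beat_times) < 4) stop("need at least 4 beats")
  n <- length(rr$intervals)
  mid <- (rr$beat_times[-1] + rr$beat_times[-(n + 1)]) / 2
  use <- rr$flags != "artifact"
  if (sum(use) < 4) stop("too few usable intervals")
  hrv <- 60000 / rr$intervals[use]
  f <- stats::splinefun(mid[use], hrv, method = "natural")
  t0 <- mid[use][1]
  t1 <- mid[use][sum(use)]
  tg <- seq(t0, t1, by = 1 / fs_out)
  hr <- f(tg)
  hr <- pmax(hr, 1e-6)
  hr_curve(tg, hr, fs_out)
}
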