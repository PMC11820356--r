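#' Evaluate paced-frequency trials
#'
#' Computes, for each paced segment, the three RF-selection metrics:
#' mean per-breath peak-to-trough heart-rate amplitude, LF/(LF+HF)
#' coherence ratio, and the phase-locking value against the pacer.
#' Breath-cycle windows are derived from the pacer schedule
#' (duration `60/freq` s from the segment start).
#'
#' @param session A list of trials, each a list with `freq` (breaths/min),
#'   `rr` (an [rr_series()]) and `resp` (list `t`, `phase` giving the
#'   pacer phase trace over the segment). At least 3 distinct frequencies.
#' @param min_duration Minimum valid segment length (s), default 120.
#'   Shorter segments are excluded with a warning.
#' @return A data.frame of class `frequency_trials` with one row per valid
#'   trial: `freq`, `mean_amp`, `lf_ratio`, `plv`, `sdnn`, `rmssd`,
#'   `pnn50`.
#' @export
evaluate_trials <- function(session, min_duration = 120) {
  freqs <- vapply(session, function(s) s$freq, numeric(1))
  if (anyDuplicated(freqs)) stop("duplicate trial frequency")
  if (length(unique(freqs)) < 3) stop("need at least 3 distinct frequencies")
  rows <- lapply(session, function(s) {
    if (is.null(s$rr)) {
      warning("trial at ", s$freq, " BPM has no usable beats; excluded")
      return(NULL)
    }
    span <- diff(range(s$rr$beat_times))
    if (span < min_duration) {
      warning("trial at ", s$freq, " BPM spans only ", round(span),
              " s (< ", min_duration, " s); excluded")
      return(NULL)
    }
    hr <- instantaneous_hr(s$rr, fs_out = 4)
    cycle <- 60 / s$freq
    bounds <- seq(0, span + cycle, by = cycle)
    amp <- breath_amplitudes(hr, bounds)
    sp <- spectral_metrics(hr)
    resp_on_grid <- stats::approx(s$resp$t, s$resp$phase, xout = hr$t,
                                  rule = 2)$y
    ps <- phase_synchrony(hr, resp_on_grid, pacing_freq = s$freq / 60)
    td <- time_domain_metrics(s$rr)
    data.frame(freq = s$freq, mean_amp = amp$mean_amp,
               lf_ratio = sp$lf_ratio, plv = ps$plv,
               sdnn = td$sdnn, rmssd = td$rmssd, pnn50 = td$pnn50)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no valid trials")
  class(out) <- c("frequency_trials", "data.frame")
  out
}

# Competition ranks on descending metric values: exact ties share the
# better (smaller) rank.
competition_rank_desc <- function(x) {
  rank(-x, ties.method = "min")
}

#' Rank table for the three RF-selection metrics
#'
#' Metric values are first rounded to their measurement resolution --
#' differences smaller than the sampling uncertainty of a single 3-min
#' trial carry no ordering information -- and then competition-ranked in
#' descending order; exact ties share the better rank.
#'
#' @param trials A [evaluate_trials()] result (or any data.frame with
#'   `freq`, `mean_amp`, `lf_ratio`, `plv`).
#' @param resolution Named ranking resolutions; defaults 0.1 beats/min
#'   for amplitude, 0.01 for the coherence ratio and 0.02 for the
#'   phase-locking value (roughly each estimator's sampling SE over a
#'   single 3-min trial). Set all to 0 to rank on exact values.
#' @return A list of class `rank_table`: `freq`, per-metric rank vectors
#'   (`amp`, `lf_ratio`, `plv`) and per-metric `top3` frequency sets
#'   (frequencies with competition rank <= 3).
#' @export
rank_trials <- function(trials,
                        resolution = c(amp = 0.1, lf_ratio = 0.01,
                                       plv = 0.02)) {
  snap <- function(x, res) if (res > 0) round(x / res) * res else x
  rk <- list(amp = competition_rank_desc(snap(trials$mean_amp,
                                              resolution[["amp"]])),
             lf_ratio = competition_rank_desc(snap(trials$lf_ratio,
                                                   resolution[["lf_ratio"]])),
             plv = competition_rank_desc(snap(trials$plv,
                                              resolution[["plv"]])))
  top3 <- lapply(rk, function(r) trials$freq[r <= 3])
  structure(list(freq = trials$freq, ranks = rk, top3 = top3),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  ord <- function(m) paste(x$freq[order(x$ranks[[m]], x$freq)],
                           collapse = "/")
  cat("amp:      ", ord("amp"), "\n")
  cat("lf_ratio: ", ord("lf_ratio"), "\n")
  cat("plv:      ", ord("plv"), "\n")
  invisible(x)
}

rf_decision <- function(rf, candidates, rule_used, evidence) {
  structure(list(rf = rf, candidates = candidates, rule_used = rule_used,
                 evidence = evidence),
            class = "rf_decision")
}

#' @export
print.rf_decision <- function(x, ...) {
  cat("RF ", x$rf, " BPM  (rule: ", x$rule_used, "; candidates: ",
      paste(x$candidates, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Stepped-and-ranked resonance-frequency selection
#'
#' Ranks the trial frequencies in descending order of each of the three
#' metrics (amplitude, coherence ratio, phase synchrony) and intersects
#' the per-metric top-3 sets. A unique intersection member is the RF;
#' with several members the tie is broken by the configured rule; with an
#' empty intersection the RF minimises the sum of its three ranks (ties
#' again by amplitude).
#'
#' @param trials A [evaluate_trials()] result with at least 3 valid
#'   trials.
#' @param tiebreak `"amplitude"` (largest mean peak-to-trough amplitude,
#'   the default) or `"majority"` (most first-place ranks, then
#'   amplitude).
#' @return An `rf_decision`: `rf` (breaths/min), `candidates` (the top-3
#'   intersection), `rule_used` (`intersection_unique`,
#'   `amplitude_tiebreak`, `majority_tiebreak` or `fallback_ranksum`) and
#'   `evidence` (the [rank_trials()] table).
#' @export
stepped_and_ranked <- function(trials, tiebreak = c("amplitude", "majority")) {
  tiebreak <- match.arg(tiebreak)
  if (nrow(trials) < 3) stop("need at least 3 valid trials")
  rt <- rank_trials(trials)
  candidates <- Reduce(intersect, rt$top3)
  amp_of <- function(f) trials$mean_amp[match(f, trials$freq)]
  break_tie <- function(cand) {
    if (tiebreak == "majority") {
      firsts <- vapply(cand, function(f) {
        i <- match(f, trials$freq)
        sum(vapply(rt$ranks, function(r) r[i] == 1L, logical(1)))
      }, numeric(1))
      cand <- cand[firsts == max(firsts)]
      if (length(cand) == 1) return(list(rf = cand, rule = "majority_tiebreak"))
    }
    a <- amp_of(cand)
    best <- cand[a == max(a)]
    list(rf = min(best),
         rule = if (tiebreak == "majority") "majority_tiebreak"
                else "amplitude_tiebreak")
  }
  if (length(candidates) == 1) {
    return(rf_decision(candidates, candidates, "intersection_unique", rt))
  }
  if (length(candidates) > 1) {
    b <- break_tie(candidates)
    return(rf_decision(b$rf, candidates, b$rule, rt))
  }
  # empty intersection: minimal rank-sum over all frequencies
  rsum <- rt$ranks$amp + rt$ranks$lf_ratio + rt$ranks$plv
  pool <- trials$freq[rsum == min(rsum)]
  if (length(pool) > 1) {
    a <- amp_of(pool)
    pool <- min(pool[a == max(a)])
  }
  rf_decision(pool, numeric(0), "fallback_ranksum", rt)
}

#' Time-domain-only resonance-frequency selection
#'
#' RF is the frequency with the largest mean per-breath peak-to-trough
#' amplitude; an exact tie at the maximum goes to the lower frequency.
#'
#' @param trials A [evaluate_trials()] result (one trial suffices).
#' @return An `rf_decision` with `rule_used = "amplitude_only"`.
#' @export
time_domain_only_rf <- function(trials) {
  if (!nrow(trials)) stop("no valid trials")
  top <- trials$freq[trials$mean_amp == max(trials$mean_amp)]
  rf_decision(min(top), sort(top), "amplitude_only",
              if (nrow(trials) >= 3) rank_trials(trials) else NULL)
}

#' Sliding-sweep resonance-frequency assessment
#'
#' Computes the per-breath peak-to-trough heart-rate amplitude over each
#' annotated breath window, smooths it with a centred 3-breath moving
#' average, and reports the frequency of the maximising breath to two
#' decimals. Interior maxima are preferred over sweep endpoints when
#' within 2% of the global maximum; an all-equal amplitude profile
#' degenerates to the lowest-frequency breath with a warning.
#'
#' @param sweep A `breath_sweep` (see [session_sweep()]) or a list with
#'   `rr` ([rr_series()]), `cycle_starts` (s) and `cycle_freqs`
#'   (breaths/min). At least 10 breaths spanning at least 1.5 breaths/min.
#' @param endpoint_margin Endpoint-preference margin, default 0.02.
#' @param min_span Minimum swept frequency range (breaths/min), default
#'   1.5. The hybrid procedure relaxes this for its deliberately narrow
#'   fine-tuning sweep.
#' @return A list of class `sliding_result`: `rf` (breaths/min, 2 dp),
#'   `breath_freqs`, `amplitudes` (smoothed), `boundary` (logical).
#' @export
sliding_assess <- function(sweep, endpoint_margin = 0.02, min_span = 1.5) {
  n <- length(sweep$cycle_freqs)
  if (n < 10) stop("sweep too short: need at least 10 breaths")
  if (diff(range(sweep$cycle_freqs)) < min_span)
    stop("sweep too narrow: must span at least ", min_span, " breaths/min")
  hr <- instantaneous_hr(sweep$rr, fs_out = 4)
  bounds <- c(sweep$cycle_starts,
              sweep$cycle_starts[n] + 60 / sweep$cycle_freqs[n])
  raw <- numeric(n)
  for (k in seq_len(n)) {
    idx <- which(hr$t >= bounds[k] & hr$t < bounds[k + 1])
    raw[k] <- if (length(idx) >= 2) max(hr$hr[idx]) - min(hr$hr[idx]) else NA
  }
  ok <- !is.na(raw)
  f <- sweep$cycle_freqs[ok]; raw <- raw[ok]
  m <- length(raw)
  if (m < 10) stop("too few breaths with usable heart-rate coverage")
  sm <- raw
  if (m >= 3)
    sm[2:(m - 1)] <- (raw[1:(m - 2)] + raw[2:(m - 1)] + raw[3:m]) / 3
  gmax <- max(sm)
  if (diff(range(sm)) < 1e-9) {
    warning("degenerate sweep: all per-breath amplitudes equal; ",
            "returning the lowest-frequency breath")
    rf <- round(min(f), 2)
    return(structure(list(rf = rf, breath_freqs = f, amplitudes = sm,
                          boundary = FALSE), class = "sliding_result"))
  }
  interior <- seq_len(m) > 1 & seq_len(m) < m
  cand <- which(sm >= (1 - endpoint_margin) * gmax & interior)
  boundary <- FALSE
  if (length(cand)) {
    best <- cand[which.max(sm[cand])]
  } else {
    best <- which.max(sm)
    if (best == 1L || best == m) {
      boundary <- TRUE
      warning("amplitude maximum at sweep endpoint; ",
              "consider widening the sweep")
    }
  }
  structure(list(rf = round(f[best], 2), breath_freqs = f,
                 amplitudes = sm, boundary = boundary),
            class = "sliding_result")
}

#' Hybrid resonance-frequency determination
#'
#' Runs a sliding sweep restricted to +-0.5 breaths/min around a
#' stepped-and-ranked decision and clamps the sliding result to that
#' range.
#'
#' @param stepped An `rf_decision` from [stepped_and_ranked()].
#' @param sweep_fn A function `(lo, hi) -> breath_sweep` producing a sweep
#'   over the requested frequency range.
#' @param halfwidth Fine-tuning half-range (breaths/min), default 0.5.
#' @return A list of class `hybrid_result`: `rf`, `range`, `stepped_rf`,
#'   `sliding` (the [sliding_assess()] result).
#' @export
hybrid_rf <- function(stepped, sweep_fn, halfwidth = 0.5) {
  if (!inherits(stepped, "rf_decision")) stop("stepped must be an rf_decision")
  lo <- stepped$rf - halfwidth
  hi <- stepped$rf + halfwidth
  sweep <- sweep_fn(lo, hi)
  sl <- sliding_assess(sweep, min_span = 1.8 * halfwidth)
  rf <- min(max(sl$rf, lo), hi)
  if (rf != sl$rf)
    warning("sliding result ", sl$rf, " clamped to [", lo, ", ", hi, "]")
  structure(list(rf = rf, range = c(lo, hi), stepped_rf = stepped$rf,
                 sliding = sl),
            class = "hybrid_result")
}
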