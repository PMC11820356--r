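test_that("evaluate_trials guards its inputs", {
  prof <- subject_profile(rf_true = 5.5, sigma_rr = 0, seed = 301)
  ses <- simulate_session(prof, build_stepped_protocol())
  trials <- session_trials(ses)

  full <- suppressWarnings(evaluate_trials(trials))
  expect_equal(nrow(full), 8)
  expect_true(all(is.finite(full$mean_amp)))
  expect_true(all(is.finite(full$lf_ratio)))
  expect_true(all(is.finite(full$plv)))

  # one segment too short -> excluded with warning
  short <- trials
  keep <- short[[2]]$rr$beat_times < 30
  short[[2]]$rr <- rr_series(short[[2]]$rr$beat_times[keep])
  expect_warning(out <- evaluate_trials(short), "excluded")
  expect_equal(nrow(out), 7)

  dup <- trials
  dup[[2]]$freq <- dup[[1]]$freq
  expect_error(evaluate_trials(dup), "duplicate")
})

test_that("stepped_and_ranked reproduces the published worked example", {
  trials <- example_rank_trials()
  dec <- stepped_and_ranked(trials)
  expect_equal(dec$rf, 4.5)
  expect_setequal(dec$candidates, c(4.5, 5.0))
  expect_equal(dec$rule_used, "amplitude_tiebreak")
  # the full per-metric orderings behind the decision
  rt <- dec$evidence
  ord <- function(m) rt$freq[order(rt$ranks[[m]], rt$freq)]
  expect_equal(ord("amp"), c(4.5, 5.0, 5.5, 6.0, 6.5))
  expect_equal(ord("lf_ratio"), c(4.5, 5.0, 6.0, 6.5, 5.5))
  expect_equal(ord("plv"), c(4.5, 5.0, 6.5, 6.0, 5.5))
})

test_that("a frequency ranked first everywhere is selected", {
  tr <- trials_df(c(5, 5.5, 6), c(9, 12, 8), c(0.7, 0.9, 0.6),
                  c(0.6, 0.9, 0.5))
  dec <- stepped_and_ranked(tr)
  expect_equal(dec$rf, 5.5)
  expect_true(5.5 %in% dec$candidates)
})

test_that("empty-intersection fallback equals brute-force rank-sum search", {
  # adversarial: disjoint top-3 sets over 9 frequencies
  set.seed(12)
  freq <- seq(4.5, 8.5, by = 0.5)
  for (rep in 1:20) {
    amp <- sample(seq(5, 45, by = 5))
    lf <- sample(seq(0.1, 0.9, by = 0.1))
    plv <- sample(seq(0.05, 0.85, by = 0.1))
    tr <- trials_df(freq, amp, lf, plv)
    dec <- stepped_and_ranked(tr)
    if (dec$rule_used != "fallback_ranksum") next
    rsum <- rank(-amp, ties.method = "min") +
      rank(-lf, ties.method = "min") + rank(-plv, ties.method = "min")
    best <- freq[rsum == min(rsum)]
    if (length(best) > 1) best <- best[which.max(amp[freq %in% best])]
    expect_equal(dec$rf, min(best))
  }
})

test_that("rankings are invariant under a monotone transform of one
           metric", {
  tr <- example_rank_trials()
  tr2 <- tr
  tr2$lf_ratio <- exp(5 * tr2$lf_ratio)     # monotone increasing
  d1 <- stepped_and_ranked(tr)
  d2 <- stepped_and_ranked(tr2)
  expect_equal(d2$rf, d1$rf)
  expect_equal(d2$evidence$ranks$lf_ratio, d1$evidence$ranks$lf_ratio)
})

test_that("majority tiebreak is available as the alternative rule", {
  # 5.0 ranks first in two metrics, 4.5 has the largest amplitude
  tr <- trials_df(c(4.5, 5.0, 5.5, 6.0),
                  mean_amp = c(20, 18, 10, 8),
                  lf_ratio = c(0.80, 0.95, 0.70, 0.60),
                  plv = c(0.70, 0.90, 0.60, 0.50))
  expect_equal(stepped_and_ranked(tr, tiebreak = "amplitude")$rf, 4.5)
  expect_equal(stepped_and_ranked(tr, tiebreak = "majority")$rf, 5.0)
})

test_that("time-domain-only selection maximises amplitude with the
           declared tie rule", {
  tr <- eval_stepped(5.5, seed = 301)
  expect_equal(time_domain_only_rf(tr)$rf, 5.5)

  tie <- trials_df(c(5.0, 5.5, 6.0), c(12, 12, 8), c(0.9, 0.8, 0.7),
                   c(0.9, 0.8, 0.7))
  expect_equal(time_domain_only_rf(tie)$rf, 5.0)

  single <- trials_df(6.0, 10, 0.8, 0.8)
  expect_equal(time_domain_only_rf(single)$rf, 6.0)
})

test_that("sliding assessment finds the resonance in a clean sweep and
           handles degenerate profiles", {
  prof <- subject_profile(rf_true = 5.0, sigma_rr = 0, a_bg = 0, seed = 11)
  proto <- pacer_protocol("sliding", sweep_from = 8, sweep_to = 4.5,
                          sweep_duration = 192)
  sweep <- session_sweep(simulate_session(prof, proto))
  expect_gte(length(sweep$cycle_freqs), 20)
  res <- sliding_assess(sweep)
  expect_gte(res$rf, 4.75)
  expect_lte(res$rf, 5.25)
  expect_true(res$rf >= min(sweep$cycle_freqs) - 1e-9 &&
                res$rf <= max(sweep$cycle_freqs) + 1e-9)

  # all amplitudes equal -> lowest frequency with degeneracy warning
  flat_sweep <- list(
    rr = rr_from_intervals(rep(800, 300)),
    cycle_starts = cumsum(c(0, 60 / seq(8, 4.7, by = -0.3)))[1:12],
    cycle_freqs = seq(8, 4.7, by = -0.3))
  expect_warning(fr <- sliding_assess(flat_sweep), "degenerate")
  expect_equal(fr$rf, 4.7)

  expect_error(sliding_assess(list(rr = flat_sweep$rr,
                                   cycle_starts = flat_sweep$cycle_starts[1:5],
                                   cycle_freqs = flat_sweep$cycle_freqs[1:5])),
               "short")
})

test_that("monotone amplitude to the sweep end returns the endpoint with a
           boundary warning", {
  # amplitude strictly increasing toward the final (lowest) frequency:
  # subject resonant below the swept range, no masking modulation
  prof <- subject_profile(rf_true = 4.2, sigma_rr = 0, a_bg = 0, a_hf = 0,
                          seed = 3)
  proto <- pacer_protocol("sliding", sweep_from = 8, sweep_to = 6,
                          sweep_duration = 240)
  sweep <- session_sweep(simulate_session(prof, proto))
  expect_warning(res <- sliding_assess(sweep), "endpoint")
  expect_true(res$boundary)
  expect_equal(res$rf, round(min(sweep$cycle_freqs), 2))
})

test_that("sliding output always lies within the swept range", {
  set.seed(10)
  for (rep in 1:4) {
    prof <- subject_profile(rf_true = runif(1, 4.6, 6.4),
                            seed = sample.int(1e6, 1))
    proto <- pacer_protocol("sliding", sweep_from = 8, sweep_to = 4.5,
                            sweep_duration = 300)
    sweep <- session_sweep(simulate_session(prof, proto))
    res <- suppressWarnings(sliding_assess(sweep))
    expect_gte(res$rf, min(sweep$cycle_freqs) - 0.005)
    expect_lte(res$rf, max(sweep$cycle_freqs) + 0.005)
  }
})

test_that("hybrid fine-tuning stays inside the +-0.5 BPM window", {
  prof <- subject_profile(rf_true = 4.8, sigma_rr = 0, a_bg = 0, seed = 12)
  dec <- stepped_and_ranked(eval_stepped(4.8, seed = 12, a_bg = 0))
  expect_true(dec$rf %in% c(4.5, 5.0))
  seen <- new.env()
  hy <- hybrid_rf(dec, function(lo, hi) {
    seen$range <- c(lo, hi)
    proto <- pacer_protocol("sliding", sweep_from = hi, sweep_to = lo,
                            sweep_duration = 240)
    session_sweep(simulate_session(prof, proto))
  })
  expect_equal(seen$range, c(dec$rf - 0.5, dec$rf + 0.5))
  expect_gte(hy$rf, dec$rf - 0.5)
  expect_lte(hy$rf, dec$rf + 0.5)
  expect_gte(hy$rf, 4.55)
  expect_lte(hy$rf, 5.05)
})
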