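test_that("time-domain metrics match direct arithmetic", {
  td <- time_domain_metrics(rr_from_intervals(rep(1000, 10)))
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(td$pnn50, 0)

  td <- time_domain_metrics(rr_from_intervals(c(800, 810, 790, 805)))
  expect_equal(td$sdnn, sd(c(800, 810, 790, 805)))
  expect_equal(td$sdnn, 8.539126, tolerance = 1e-6)
  expect_equal(td$rmssd, sqrt(mean(c(10, -20, 15)^2)))
  expect_equal(td$rmssd, 15.54563, tolerance = 1e-6)
  expect_equal(td$pnn50, 0)

  td <- time_domain_metrics(rr_from_intervals(c(900, 1000, 900, 1000, 900)))
  expect_equal(td$pnn50, 100)

  expect_error(time_domain_metrics(rr_series(c(0, 0.8))), "SDNN")
  # artifact-flagged intervals excluded
  td <- time_domain_metrics(rr_from_intervals(
    c(800, 800, 2500, 800, 800),
    flags = c("ok", "ok", "artifact", "ok", "ok")))
  expect_equal(td$sdnn, 0)
})

test_that("time-domain metrics are shift-invariant", {
  set.seed(2)
  iv <- 800 + rnorm(100, 0, 30)
  a <- time_domain_metrics(rr_from_intervals(iv))
  b <- time_domain_metrics(rr_from_intervals(iv + 150))
  expect_equal(a$sdnn, b$sdnn, tolerance = 1e-12)
  expect_equal(a$rmssd, b$rmssd, tolerance = 1e-12)
  expect_equal(a$pnn50, b$pnn50)
})

test_that("spectral metrics separate LF and HF band energy", {
  lf_curve <- make_hr(function(t) 70 + 5 * sin(2 * pi * 0.1 * t), 300)
  sp <- spectral_metrics(lf_curve)
  expect_gte(sp$lf_ratio, 0.95)

  hf_curve <- make_hr(function(t) 70 + 5 * sin(2 * pi * 0.25 * t), 300)
  expect_lte(spectral_metrics(hf_curve)$lf_ratio, 0.05)

  # white noise: ratio near the band-width ratio 0.11/0.36
  # (Monte-Carlo oracle: mean over 5 seeded replicates at 300 s)
  set.seed(31)
  ratios <- replicate(5, {
    noise <- make_hr(function(t) 70 + rnorm(length(t), 0, 3), 300)
    spectral_metrics(noise)$lf_ratio
  })
  expect_lt(abs(mean(ratios) - 0.11 / 0.36), 0.1)

  expect_error(spectral_metrics(make_hr(function(t) 70 + 0 * t, 60)),
               "120")
  expect_warning(
    spectral_metrics(make_hr(function(t) 70 + sin(2 * pi * 0.1 * t), 140)),
    "single-segment")
})

test_that("lf and hf shares are complementary by construction", {
  set.seed(8)
  x <- make_hr(function(t) 70 + 2 * sin(2 * pi * 0.09 * t) +
                 rnorm(length(t), 0, 1.5), 300)
  sp <- spectral_metrics(x)
  hf_share <- sp$hf_power / (sp$lf_power + sp$hf_power)
  expect_equal(sp$lf_ratio + hf_share, 1, tolerance = 1e-12)
  expect_true(all(sp$psd >= 0))
})

test_that("breath amplitudes follow the cycle-window definition", {
  hr <- make_hr(function(t) 70 + 5 * sin(2 * pi * 0.1 * t), 100)
  ba <- breath_amplitudes(hr, seq(0, 100, by = 10))
  expect_equal(length(ba$per_cycle), 10)
  expect_true(all(abs(ba$per_cycle - 10) < 0.1))

  flat <- breath_amplitudes(make_hr(function(t) 70 + 0 * t, 50),
                            seq(0, 50, 10))
  expect_true(all(flat$per_cycle == 0))

  # mean of two known cycles
  two <- breath_amplitudes(
    make_hr(function(t) 70 + ifelse(t < 10, 2, 6) * sin(2 * pi * 0.1 * t),
            20), c(0, 10, 20))
  expect_equal(two$mean_amp, mean(two$per_cycle))
  expect_error(breath_amplitudes(make_hr(function(t) 70 + 0 * t, 5),
                                 c(10, 20)), "cycle")
})

test_that("breath amplitudes are invariant under an HR offset", {
  hr1 <- make_hr(function(t) 70 + 4 * sin(2 * pi * 0.09 * t), 120)
  hr2 <- make_hr(function(t) 95 + 4 * sin(2 * pi * 0.09 * t), 120)
  b1 <- breath_amplitudes(hr1, seq(0, 120, by = 1 / 0.09))
  b2 <- breath_amplitudes(hr2, seq(0, 120, by = 1 / 0.09))
  expect_equal(b1$per_cycle, b2$per_cycle, tolerance = 1e-9)
})

test_that("phase synchrony behaves at its limits", {
  f <- 0.1
  t <- seq(0, 300, by = 0.25)
  resp <- 2 * pi * f * t
  hr <- hr_curve(t, 70 + 5 * sin(resp + 1.1), 4)
  ps <- phase_synchrony(hr, resp, f)
  expect_gt(ps$plv, 0.98)
  expect_true(ps$plv <= 1)

  # independent white noise
  set.seed(77)
  hrn <- hr_curve(t, 70 + rnorm(length(t), 0, 3), 4)
  expect_lt(phase_synchrony(hrn, resp, f)$plv, 0.2)

  expect_error(phase_synchrony(hr, resp[-1], f), "grid")
  expect_error(phase_synchrony(hr, resp, 0.3), "0.17")
})

test_that("plv lies in [0,1] and is invariant under a global resp phase
           offset", {
  t <- seq(0, 240, by = 0.25)
  set.seed(4)
  for (rep in 1:3) {
    hr <- hr_curve(t, 70 + 3 * sin(2 * pi * 0.1 * t + runif(1, 0, 2 * pi)) +
                     rnorm(length(t), 0, runif(1, 0.5, 3)), 4)
    resp <- 2 * pi * 0.1 * t
    p0 <- phase_synchrony(hr, resp, 0.1)
    p1 <- phase_synchrony(hr, resp + 2.345, 0.1)
    expect_gte(p0$plv, 0)
    expect_lte(p0$plv, 1)
    expect_equal(p0$plv, p1$plv, tolerance = 1e-9)
  }
})

test_that("training-effect report computes during/pre ratios with guards", {
  set.seed(6)
  base <- 900 + rnorm(90, 0, 20)
  pre <- rr_from_intervals(base)
  same <- training_effect_report(pre, pre, pre)
  expect_equal(same$ratios$sdnn, 1)
  expect_equal(same$ratios$rmssd, 1)

  during <- rr_from_intervals(900 + (base - 900) * 2)
  rep2 <- training_effect_report(pre, during, pre)
  expect_equal(rep2$ratios$sdnn, 2, tolerance = 1e-9)

  flat <- rr_from_intervals(rep(900, 90))
  rep3 <- training_effect_report(flat, pre, flat)
  expect_true(is.na(rep3$ratios$pnn50))

  expect_error(training_effect_report(rr_from_intervals(rep(900, 10)),
                                      pre, pre), "60 s")
})
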