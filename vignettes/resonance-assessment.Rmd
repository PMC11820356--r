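---
title: "Resonance-frequency assessment: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resonance-frequency assessment: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfbreathe)
```

## The problem

Heart-rate-variability biofeedback paces a person's breathing at their
*resonance frequency* (RF): the breathing rate, usually between 4.5 and
6.5 breaths/min, at which the baroreflex feedback loop resonates and
respiratory sinus arrhythmia (RSA) is maximally amplified. RF differs
between individuals and drifts with physiological state, so it should be
re-assessed regularly — but the classical assessment requires a
therapist to compare HRV metrics across paced trials by eye.
`rfbreathe` automates that judgement so assessment can run unattended in
home settings, and ships a ground-truthed simulator so every part of the
pipeline can be validated without clinical recordings.

## The three assessment metrics

Each paced trial (one breathing frequency, held for minutes) is scored
by three complementary metrics:

* **Mean peak-to-trough amplitude** (beats/min): for each breath-cycle
  window `[start_k, start_{k+1})`, `max(HR) − min(HR)` on the
  instantaneous heart-rate curve; averaged over cycles. Directly
  measures RSA magnitude.
* **Coherence ratio** `LF/(LF+HF)` (dimensionless): the fraction of
  oscillatory power concentrated in the low-frequency band. Paced slow
  breathing lives in LF (0.04–0.15 Hz); spontaneous respiratory
  modulation lives in HF (0.15–0.40 Hz, Task-Force band edges — the
  source material names the metric but not the edges).
* **Phase synchrony** (PLV, dimensionless in [0, 1]): the
  phase-locking value between the cardiac oscillation and the pacer,
  `|mean(exp(i·Δφ))|`, with Δφ from Hilbert phases after a zero-phase
  4th-order Butterworth band-pass at the pacing frequency ± 0.03 Hz.

Estimator details that matter:

* The heart-rate curve places `60000/RR` at interval midpoints and
  interpolates with a natural cubic spline onto a 4 Hz grid (natural
  rather than an extrapolating end condition, to avoid edge overshoot
  that would inflate the first and last breath windows).
* The spectral input is the evenly resampled RR tachogram in ms
  (mean-removed), estimated by Welch's method: 120 s Hann segments,
  50 % overlap, per-segment linear detrend, with the final segment
  placed flush with the record end so that a 3-min trial genuinely
  yields two segments. Records shorter than 1.25 segments fall back to
  a single-segment periodogram with a warning. Band powers are
  trapezoidal integrals over half-open bands.
* PLV is computed on the RR tachogram rather than on heart rate. The
  two differ by the reciprocal map `HR = 60000/RR`, which is nonlinear:
  at resonance-sized oscillations (±100 ms on an 800 ms baseline) the
  map injects amplitude-dependent harmonic and phase artefacts that
  *depress* PLV exactly where it should peak. RR is the physiologically
  linear substrate; in the small-oscillation limit the two phases
  differ by exactly π, which is added back so the reported lag is
  HR-referenced. Additionally, 1.5 pacing cycles are trimmed from each
  end of the phase-difference series before averaging: filter and
  Hilbert edge transients corrupt a fixed number of cycles, which is a
  proportionally larger bias for slow pacing (only ~12 cycles of
  4.5 BPM fit into a trial) and otherwise tilts PLV against exactly the
  frequencies of interest.

## Stepped-and-ranked selection

`stepped_and_ranked()` ranks the trial frequencies in descending order
of each metric, takes each metric's top 3, and intersects:

* a unique intersection member is the RF;
* several members: the one with the largest mean amplitude wins
  (`tiebreak = "amplitude"`, the default). A `"majority"` rule (most
  first-place ranks, then amplitude) is also provided, because manual
  raters sometimes prefer the amplitude-first-ranked frequency — the
  two rules genuinely disagree on some inputs and neither is uniquely
  "correct";
* an empty intersection falls back to the frequency with the minimal
  sum of its three ranks (ties again by amplitude). The source
  procedure leaves this case undefined; rank-sum is the natural
  extension and is tested against exhaustive search.

**Ranking resolution.** Ranks are computed on metric values rounded to
a per-metric measurement resolution — 0.1 beats/min for amplitude, 0.01
for the coherence ratio, 0.02 for PLV — with exact ties sharing the
better competition rank. The resolutions approximate each estimator's
sampling SE over a single 3-min trial (for PLV: roughly `1/√N_eff` with
`N_eff ≈ 10` independent phase stretches). Ranking on differences far
below estimator noise turns top-3 membership into a lottery: in
simulation, exact-value ranking frequently excluded the true RF from
one metric's top 3 by margins of 0.005 or less. Passing
`resolution = c(amp = 0, lf_ratio = 0, plv = 0)` restores exact-value
ranking.

`time_domain_only_rf()` uses the amplitude ranking alone (ties to the
lower frequency) — the faster variant appropriate when frequency-domain
metrics are unavailable.

## Sliding and hybrid assessment

`sliding_assess()` scores a continuous sweep of breath lengths: one
amplitude per annotated breath, smoothed by a centred 3-breath moving
average; the RF is the frequency of the maximising breath, reported to
two decimals. Interior maxima are preferred over sweep endpoints when
within 2 % of the global maximum; a monotone profile returns the
endpoint with a boundary warning, and a flat profile degenerates to the
lowest-frequency breath with a warning.

`hybrid_rf()` runs a sliding sweep restricted to ±0.5 breaths/min
around a stepped decision and clamps the result to that window. The
generic sliding precondition (span ≥ 1.5 breaths/min) would reject this
deliberately narrow sweep, so the hybrid relaxes it via `min_span` —
the two requirements are contradictory as stated, and the narrow-sweep
reading is the one that makes the hybrid well-defined.

## Pacing, adaptation and monitoring

The standard assessment protocol descends from 8 to 4.5 breaths/min in
0.5 BPM steps, 180 s per step (8 steps, 24 min). During training, when
the last three per-breath amplitudes are strictly decreasing the
guiding frequency moves 0.25 breaths/min toward the resting rate
(default 12 breaths/min, a profile parameter; the source states the
increment but not the resting value). "Strictly decreasing over three
breaths" operationalises "continuous decline", which is otherwise
unquantified. Deviation alerts require *repeated* deviations: at least
3 consecutive breaths more than 1.0 breaths/min off target, or at least
3 consecutive breaths below half the baseline depth. Adherence is
per ISO calendar week: at least 4 sessions of at least 15 min.

## The simulator and what it establishes

`simulate_session()` generates beats by forward interval stepping,
`t_{k+1} = t_k + RR(t_k)/1000`, from the continuous process

```
RR(t) = rr0
      + a_rsa · gain(f(t)) · sin(φ_resp(t) + phase(f(t)) + π)
      + a_hf · sin(2π · f_hf · t)
      + bg(t)
      + σ_rr · w(t)
```

with the second-order resonance `gain = 1/√((1−r²)² + (2ζr)²)`,
`phase = −atan2(2ζr, 1−r²)`, `r = f/rf_true`. Defaults (units,
rationale):

| parameter | default | meaning |
|---|---|---|
| `rr0` | 800 ms | baseline interval (75 beats/min, healthy adult) |
| `a_rsa` | 20 ms | RSA modulation at unit gain; ×5 at resonance gives a realistic ~200 ms peak-trough swing while staying within the quasi-linear range of beat sampling |
| `zeta` | 0.1 | damping; gain 5 at resonance, and the gain peak sits within 1 % of `rf_true` (the peak of this transfer function is at `r = √(1−2ζ²)`, so large ζ shifts it visibly below `rf_true` — see Limitations) |
| `a_hf` | 10 ms | spontaneous HF modulation at `f_hf` = 0.25 Hz, so the coherence ratio has HF power to discriminate against |
| `a_bg` | 20 ms RMS | background low-frequency variability: a 48-component random-phase sinusoid bank over 0.04–0.17 Hz (Mayer-wave / intrinsic baroreflex activity) |
| `sigma_rr` | 5 ms | white measurement/vagal noise per beat |

The background term is essential, not decorative: without it the
simulator is deterministic, PLV and the coherence ratio saturate near 1
at *every* paced frequency, and their rankings are decided by numerical
artefacts. With background variability in-band, both metrics become
signal-to-noise ratios that genuinely peak at resonance — which is the
premise of the multi-metric method. The band extends to 0.17 Hz so that
every pacing passband (up to 0.133 + 0.03 Hz) sees the same background
level; ending the band mid-passband made high-frequency trials look
spuriously clean.

`session_trials()` excludes the first 20 s of each step: the simulator
re-tunes its gain instantaneously at a step boundary, and the resulting
waveform transient otherwise leaks broadband power into precisely the
resonance trial's spectrum. Physiological re-entrainment after a rate
change takes a couple of breaths, so a settle-in exclusion is also what
one would do with real recordings.

What a green test establishes: the selection logic recovers a known
resonance through the full pipeline (beats → curves → metrics → ranks)
under realistic noise, at the stated rates (exact grid recovery in the
deterministic world; ≥ 90 % within 0.5 BPM at σ_RR = 10 ms across 50
seeded replicates — observed 96–100 %). What it does not establish:
agreement with human raters, robustness to ectopy/artifact morphology,
electrode or respiration-sensor behaviour, or any claim about training
efficacy — the simulator has no slow autonomic adaptation.

## Statistical conventions

* Bland–Altman: differences `x − y`, sample (n−1) SD, limits
  `mean ± 1.96·SD`. The bundled ten-pair comparison reproduces its
  published statistics only under exactly these conventions.
* Descriptive table rows use the population (divide-by-n) SD — the
  convention under which the same publication's summary rows reproduce.
  Both are deliberately implemented and bound to the statistic each
  reproduces.
* Paired Wilcoxon: zeros dropped (classical, not Pratt), mid-ranks for
  ties, statistic `W = min(W⁺, W⁻)`. The null distribution is exact for
  up to 25 effective pairs via the shift algorithm — algebraically
  identical to enumerating all 2ⁿ sign assignments, and tested against
  brute-force enumeration for n ≤ 10 — with a tie-corrected normal
  approximation beyond. Two-sided p is `min(1, 2·min(P≤, P≥))`.
* The pre/post HRV improvement test is a one-sided ("post > pre")
  paired Wilcoxon per metric; the unnamed test behind the published
  "p < 0.05" claim is taken to be of this family.

## Numerical choices and degenerate inputs

* Intervals are clipped to [300, 2000] ms during simulation; clipped
  sessions carry a flag and a warning.
* `clean_rr(policy = "drop")` removes artifact intervals and compacts
  the series (beat times after a dropped interval are not preserved);
  this is what makes cleaning idempotent. Interpolation is linear over
  the midpoints of neighbouring good intervals.
* RR CSVs store one row per beat with the final interval repeated so
  files round-trip; intervals are written at µs precision (round-trip
  error ≪ the 10⁻³ ms contract).
* The beat-average of a modulated RR series is biased below `rr0` by
  ≈ A²/(2·rr0) (≈ 6 ms at a 100 ms swing): a property of beat
  averaging, not an implementation error. Mean-interval checks are
  therefore done off-resonance.

## Limitations

* Under the declared transfer function the amplitude peak sits at
  `rf_true·√(1−2ζ²)`. For ζ ≳ 0.22 this is more than half a grid step
  below `rf_true`, so "recovers the nearest grid frequency" cannot hold
  for heavily damped subjects as a matter of algebra, not code. The
  cohort range is ζ ∈ [0.08, 0.15].
* In the stochastic world, exact-grid recovery at σ_RR = 0 is ~95 %
  with all misses on an adjacent grid frequency: background variability
  occasionally pushes the true frequency out of one metric's top 3.
  This mirrors the discordance real raters show on the same data and is
  why the noisy-recovery criterion is stated as within-0.5-BPM.
* The sliding estimator inherits per-breath amplitude noise; on fast
  sweeps with default background it scatters ~±0.25 BPM and can prefer
  a sweep endpoint. Slow sweeps (≥ 240 s) behave markedly better.
* The hybrid's fine-tuning sweep must be a new acquisition; the
  file-based CLI can only synthesise it for simulated subjects (from
  the truth sidecar).
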