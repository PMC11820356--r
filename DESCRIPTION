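Package: rfbreathe
Title: Resonance-Frequency Breathing Assessment and HRV Biofeedback Tools
Version: 0.1.0
Authors@R: person("rfbreathe", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for heart-rate-variability (HRV) biofeedback at the
    individual resonance frequency (RF). Reads and cleans RR-interval
    series, computes the time-domain, spectral, per-breath amplitude and
    phase-synchrony metrics used in RF assessment, and determines RF by
    the stepped-and-ranked multi-metric procedure, a time-domain-only
    variant, a per-breath sliding sweep, and a hybrid of the two. Includes
    paced-breathing protocol generation with adaptive frequency
    adjustment and adherence monitoring, a seeded cardiorespiratory
    simulator with a second-order baroreflex-resonance model for
    ground-truthed testing, and the Bland-Altman / exact Wilcoxon
    agreement statistics used to compare RF-determination methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
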