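Package: crpkit
Title: Continuous Relative Phase Analysis of Lower-Limb Segment Coordination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes continuous relative phase (CRP) between lower-limb
    segments (thigh, shank, foot) from sagittal segment-angle time series
    recorded during level walking and one-leg hopping. Covers the full chain
    from raw channels to coordination summaries: zero-lag Butterworth
    smoothing, ground-reaction-force contact-event detection, phase
    segmentation (stance/swing; preflight/flight/landing), time
    normalization to the 0-100% cycle, phase portraits and phase angles with
    360-degree unwrapping, CRP per segment couple, and per-phase RMS
    (in-phase vs out-of-phase coordination) and SD (coordinative
    variability) summaries, plus normality-gated paired condition
    comparisons. Includes a synthetic gait/hop trial generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
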