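Package: ssvephue
Title: Hue Tuning of Steady-State Visual Evoked Potentials in Cone-Opponent Color Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for steady-state visual evoked potential (SSVEP)
    experiments in which stimulus hue sweeps smoothly around an isoluminant hue
    circle defined in a scaled cone-contrast color space. Provides hue-sweep
    stimulus schedules, a synthetic multichannel EEG generator with elliptical
    hue-tuning ground truth, preprocessing (epoching, artifact rejection,
    average re-referencing, sector averaging), complex Gabor extraction of
    5 Hz amplitude and phase-derived latency, direct least-squares ellipse
    fitting with participant-level bootstrap confidence intervals, and
    AIC-based comparison of cone-opponent, perceptual (Munsell iso-Chroma)
    and mixed hue-tuning models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
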