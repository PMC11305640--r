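Package: ripplemtf
Title: Spectrotemporal Modulation Transfer Functions from Ripple Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for psychoacoustic analysis of spectral-temporal modulation
    sensitivity measured with dynamic rippled noise. Synthesizes moving-ripple
    stimuli from a log-spaced tone complex, runs transformed up-down adaptive
    staircases for pure-tone audiometry, fits four-parameter cumulative Weibull
    psychometric functions with guess and lapse rates, assembles threshold and
    iso-depth modulation transfer function (MTF) matrices over a density-by-
    velocity grid, and quantifies spectrum-time separability and up/down
    symmetry via singular value decomposition, permutation nulls, bias-corrected
    bootstrap confidence intervals, and mutual information. A synthetic-observer
    module generates ground-truth MTFs with controlled inseparability and
    simulates trial-level response tables so the full pipeline can be exercised
    and validated without behavioral recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
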