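Package: pc4dflow
Title: Quantification and Quality Assessment of 4D Phase-Contrast MR Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for time-resolved three-dimensional
    phase-contrast (4D flow) cardiovascular MR velocity data:
    first-order eddy-current background-phase correction, temporal
    velocity-aliasing unwrapping, reformatting of the 4D dataset onto
    arbitrary oblique 2D planes, vessel flow-curve and stroke-volume
    quantification, pathline particle tracing with blood-pool
    containment grading, and method-agreement statistics (linear
    regression, Bland-Altman percent bias, exact Wilcoxon signed-rank).
    Includes a synthetic pulsatile tube-flow phantom generator with
    analytic ground truth and acquisition-artifact operators (velocity
    noise, phase wrap, temporal blurring, prospective-gating
    truncation) for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
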