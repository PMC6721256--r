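Package: adaptindex
Title: Quantitative Index of Physiological Adaptedness
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes a composite index of physiological adaptedness from
    pre-load, post-load and recovery measurements of a biomarker panel.
    Parameters are classified as homeostatic (their load-induced deviation
    counts against adaptedness), adaptive/allostatic (their activation counts
    in favour) or indifferent, and each term can be weighted by a stability
    coefficient (one minus the baseline coefficient of variation). Supports
    single-subject comparisons, repeated-measure group designs with
    confidence intervals and significance tests, and destructively sampled
    designs where group means substitute for individual values (with a
    parametric-bootstrap uncertainty extension). Includes transcriptions of
    two published worked examples (rat swimming-exercise biochemistry and
    race-horse exercise physiology), a synthetic cohort simulator with known
    ground-truth adaptedness for validation, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
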