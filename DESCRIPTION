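Package: gazescan
Title: Eye-Head Coordination and Time-Based Visual Scanning Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for eye and head rotation recordings from
    dual-task driving-simulator experiments. Reconstructs gaze-in-space from
    eye-in-head and head-in-world yaw/pitch traces, labels areas of interest
    by ray-plane intersection with the scene geometry, quantifies eye-head
    coordination as the density-filtered regression slope of head on eye
    rotation within visual-search trials, and computes time-based transition
    entropy of eye, head and gaze scanpaths (120 ms displacement bins, first
    order Markov transition model, normalized conditional entropy). Includes
    a synthetic scanpath generator with known ground-truth parameters
    (semi-Markov area-of-interest dwells, tunable head-contribution gain and
    scan randomness) so every stage can be validated by parameter recovery,
    plus the statistical stage of the analysis (Kolmogorov-Smirnov
    distribution comparison, Box-Cox skew correction, condition-by-group
    ANOVA with effect sizes, Tukey HSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
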