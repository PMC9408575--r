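Package: moodmap
Title: Unsupervised Classification and Visualization of Mood States from
    Psychometric and Behavioral Signals
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for clustering and visualizing mood states from POMS2
    mood-component scores and behavioral signals recorded during human
    communication. Converts component scores to T-scores and the total mood
    disturbance (TMD) and friendliness (F) indicators, clusters sessions with
    a from-scratch self-organizing map (SOM), extracts category boundaries
    with a U-Matrix and attaches positive/neutral/negative semantic labels,
    extracts smile-expression frames from facial time series with a recurrent
    SOM, organizes expression prototypes with a growing hierarchical SOM, and
    computes gaze-heatmap extent and saccade counts from eye-tracking traces.
    Includes seeded synthetic-data generators emulating a 20-subject weekly
    cohort so the full pipeline is testable without human-subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
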