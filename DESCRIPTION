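Package: Glimpse
Title: Temporal Visual Salience from Multi-Observer Gaze Consistency
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Training-free estimation of temporal visual salience for
    time-varying stimuli (videos) from raw multi-observer eye-tracking
    data. The per-frame score is the fraction of pairs of gaze points,
    pooled across observers within a short temporal window, that fall
    closer than a spatial scale threshold; a windowed variant of
    Ripley's K point-pattern statistic. Also included: four heuristic
    algorithms that derive a temporal salience signal from sequences of
    spatial salience maps (windowed mutual information, global maximum,
    Gaussian-weighted spread around the salience centroid, and
    connected-component "point hypotheses"), signal-comparison metrics
    (length-normalized Euclidean distance, soft precision/recall, mean
    Jaccard index, rank correlations), an observer-subset resampling
    analysis of score convergence, and a synthetic gaze/salience-map
    generator with known attention structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    EBImage,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Visualization, CellBasedAssays
RoxygenNote: 7.3.3
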