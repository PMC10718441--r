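Package: scalestats
Title: Resampling Statistics for Cross-Cultural Musical Scale Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis of corpora of musical scales given as note
    positions in cents from the tonic. Provides three null models of scale
    generation (independent lognormal notes, within-scale step shuffling,
    step resampling), society-balanced subsampling with per-bin binomial
    tail tests and Bonferroni correction for between-scales interval
    significance, Mann-Whitney U based within-scale interval tests with
    resampled-null calibration and an intonation-noise sensitivity
    experiment, exhaustive enumeration of octave scales on a cents grid
    with equidistance and note-entropy statistics, and a two-dimensional
    embedding with density clustering for comparing scales across
    societies. A seeded synthetic corpus generator emulates the
    statistical structure of published scale databases so every analysis
    stage can be exercised without access to the original sources.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
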