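Package: boutondyn
Title: Activity and Structural Dynamics of Axonal Boutons During Motor Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for longitudinal two-photon imaging of
    corticostriatal axonal boutons in a cued lever-pushing task. Segments
    lever traces into movement bouts and labels rewarded versus unrewarded
    movements, extracts dF/F with a sliding-percentile baseline, detects
    calcium events and partitions them into peaks shared across boutons of
    an axon versus bouton-unique peaks, classifies bouton and axon
    responsiveness around movement onsets, computes PCA population
    trajectories and a trial selectivity index, bins population-activity
    statistics against movement-trajectory similarity, and quantifies
    structural bouton turnover with a nearest-neighbour-distance
    permutation test. Includes a synthetic-data generator with ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
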