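Package: trxscore
Title: Two-State Conformer Modeling and Composite Scoring for
    Time-Resolved Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Build, validate and rank two-state (reference plus triggered)
    crystallographic models assembled from pools of sampled conformers.
    Provides alternative-conformer merging with occupancy and B-factor
    bookkeeping, Kabsch superposition, real-space density validation
    (RSCC, RSZO, RSZD) on voxel grids, difference-density residue weights,
    simplified geometry validation (clashscore, bond and angle RMS),
    a min-max-normalized composite score for model ranking, ensemble RMSF
    analysis, and a synthetic two-state mixture density simulator with a
    closed-form mock occupancy refiner so the whole workflow is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
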