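Package: dyncomm
Title: Dynamic Community Detection, Tracking and Flow Visualization for
    Electrode Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects communities in time-varying electrode correlation
    networks by consensus clustering with CDF-based selection of the
    number of clusters, tracks them across timesteps by greedy
    maximum-overlap or globally optimal Jaccard matching, orders the
    resulting timeline by barycenter sweeps, and renders deterministic
    static SVG views: an alluvial cluster-evolution diagram, a K-cluster
    likelihood heatmap, and aggregated clock-glyph electrode views.
    Includes a synthetic-data generator with planted community schedules
    and activation modes for controlled evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RColorBrewer,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
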