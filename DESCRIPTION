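Package: moveclass
Title: Functional Movement Classification of Acoustic Telemetry Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies acoustically tagged aquatic animals into functional
    movement classes from passive telemetry detection logs. Computes seven
    per-individual movement covariates (detection counts, installation counts,
    mean inter-detection interval, and quantiles of consecutive-detection
    travel distance), selects the number of k-means classes with the gap
    statistic, names classes a posteriori (Residents, Occasionals, Irruptors,
    Roamers), characterizes them with Euclidean SIMPER after dispersion
    weighting and log(x+1) transformation, and builds relative-movement
    networks over receiver installations with node- and network-level metrics
    and modularity-based community detection. An agent-based detection
    simulator for four movement archetypes lets the whole workflow run and be
    tested without access to a national telemetry database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    geosphere,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
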