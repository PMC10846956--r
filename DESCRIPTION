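Package: adtkit
Title: Psychometric Analysis of Associative-Dissociative Retrieval Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for scoring and validating the associative-dissociative
    retrieval task (ADT), a latency-based measure of automatic (free
    associative) and controlled (dissociative) semantic memory retrieval.
    Implements trial screening, outlier filtering and winsorized
    inhibition-cost scoring; internal consistency (McDonald's omega,
    Cronbach's alpha), test-retest and trial-sampling reliability curves
    with Cronbach-Mesbah item selection; free-association norm cleaning,
    associative-hierarchy statistics and LogDice-weighted co-occurrence
    networks with Louvain modularity, path length, clustering and global
    efficiency; parallel-analysis PCA composites with oblimin rotation;
    paired contrasts with Cohen's d, Holm adjustment and dependent
    correlation comparison. A seeded synthetic-data generator emulates the
    full study design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tibble,
    tidyr,
    rlang,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
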