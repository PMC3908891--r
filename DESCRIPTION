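Package: tempocomm
Title: Community-Activity Structure of Temporal Networks by Non-Negative
    Tensor Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects communities and their activity timelines in temporal
    (time-stamped) contact networks by representing the network as a
    three-way adjacency tensor and decomposing it with non-negative
    PARAFAC/CP factorization, solved by alternating non-negative least
    squares with block principal pivoting. Includes the core-consistency
    (CORCONDIA) model diagnostic, component relevance scoring, a
    multi-restart selection protocol, k-means membership binarization,
    per-component activity strength, ground-truth validation (Jaccard
    matching, recall, score matrices) and spatio-temporal co-location
    analysis, plus a planted community-activity benchmark generator and
    readers for SocioPatterns-style contact edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
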