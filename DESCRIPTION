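Package: assocnet
Title: Animal Social Networks from Observation Data: Association Indices,
    Permutation Null Models and Hypothesis Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted social networks from group-based observation data
    ("gambit of the group") and directed interaction logs, using simple-ratio and
    half-weight association indices and generalized affiliation indices. Provides
    node- and network-level metrics, leading-eigenvector community detection,
    constrained data-stream and node-label permutation null models, and the
    permutation-based hypothesis tests used in behavioural ecology: the
    coefficient-of-variation test for preferred and avoided associations,
    permutation-corrected coefficients for (mixed) linear models of node metrics,
    Mantel and MRQAP (double-semi-partialling) matrix regressions, lagged
    association rates, bootstrap precision and split-half repeatability of node
    metrics, and sampling-effort power analysis relating social differentiation
    to the number of identifications per dyad. Includes seed-reproducible
    synthetic-population generators for two-area fission-fusion populations with
    gregariousness-linked sex allocation and class-dependent detection bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
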