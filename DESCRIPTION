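Package: rwrvm
Title: Disease-Gene Prioritization with Restart Random Walks and Relevance
    Vector Machine Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease genes on a weighted gene
    interaction network. A restart random walk encodes network topology
    around a set of known (seed) disease genes; the resulting diffusion
    profiles are fused with a binary gene-by-ncRNA regulation matrix to
    form kernel features; an equal-weight ensemble of three relevance
    vector machines (sparse Bayesian kernel regression fitted by type-II
    maximum likelihood) scores every gene. Includes ROC/PR metrics with
    exact tie handling, a repeated negative-sampling k-fold
    cross-validation harness for the positive-unlabeled setting, and a
    synthetic-data generator with a planted disease module for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
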