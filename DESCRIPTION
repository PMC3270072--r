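Package: grnevo
Title: Development and Evolution of Continuous-Output Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a Wagner-type transcriptional regulatory network
    model with continuously varying expression levels. A network of n
    transcription factors is an n x n interaction matrix W; an individual's
    expression state S develops by iterating S <- f(W %*% S) with a sigmoidal
    scaling function until a windowed convergence statistic falls below a
    stability threshold. The package provides the developmental dynamics,
    random genesis of viable individuals by rejection sampling, network
    evolution operators (haploid and diploid mating, gene insertion,
    duplication and deletion), the measurement layer (intraclass correlation
    of stable states, viability-rate estimation with binomial intervals,
    output-distribution uniformity, network-versus-initial-vector
    decomposition), seeded experiment runners that return tidy tables, and a
    small command-line interface with TSV/JSON interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    jsonlite,
    generics,
    yaml,
    stats,
    utils,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
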