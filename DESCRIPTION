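Package: phagevolve
Title: In Silico Evolution of Phage Genome Architectures to Match
    Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic, single-molecule simulation of transcription,
    termination, RNase cleavage and directional degradation on small
    linear phage genomes, together with an origin-fixation evolutionary
    engine with simulated annealing that evolves the placement and
    strengths of promoters, terminators and RNase cleavage sites so
    that simulated transcript time courses match user-supplied target
    expression patterns. Includes tools for gene-arrangement search,
    greedy removal of non-functional regulatory elements, and entropy
    based diversity analysis of evolved genome architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
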