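Package: wfcoal
Title: Whole-Genome Genealogies Under Coalescent and Discrete-Time
    Wright-Fisher Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates whole-genome genealogies backwards in time under
    Hudson's coalescent with recombination, a discrete-time Wright-Fisher
    (DTWF) model in which each gamete has a single diploid parent and
    meiosis places crossovers as a Poisson process along the genetic map,
    and a hybrid of the two (Wright-Fisher in the recent past, coalescent
    beyond a switch time). Records genealogies as node/edge tables and
    computes the multi-locus statistics that expose coalescent biases in
    large cohorts: surviving-lineage counts through time, identity-by-
    descent segments between sample pairs, variance in admixture ancestry
    proportions after a migration pulse, the site frequency spectrum, and
    long-range linkage disequilibrium. Ships closed-form expectations for
    IBD sharing between relatives and for ancestry variance, a monogamous
    pedigree simulator for cousin-containment probabilities, and a forward
    gene-dropping oracle used to validate them.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
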