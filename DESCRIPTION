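Package: phageprofiler
Title: Phage Genome Characterization from Reads, Fragment ANI and Domain Phyletics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational characterization of newly sequenced
    bacteriophage genomes. Summarizes per-genome features (size, GC content,
    open reading frames), detects genome termini and DNA-packaging mechanisms
    (direct terminal repeats and headful pac sites) from read-coverage and
    read-start signatures, computes fragment-based average nucleotide identity
    (ANIb) with agglomerative clustering, builds protein-domain
    presence-absence matrices clustered with Ward's method including singleton
    detection, and scores the congruence of nucleotide- and domain-based
    classifications with the adjusted Rand index. Ships a fully seeded
    synthetic phage-community generator (genomes, domain-hit tables and
    sequencing reads carrying termini-dependent coverage signatures, with
    ground-truth labels) used to validate every step end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
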