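Package: allomap
Title: Mapping Interdomain Allostery from Elastic Network Dynamics and
    Sequence Coevolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrated structure-dynamics and sequence-coevolution analysis
    for two-domain allosteric proteins such as the Hsp70 chaperone DnaK.
    Builds Gaussian and anisotropic elastic network models from residue-level
    structures, locates global hinges from slow-mode mobility profiles, and
    runs perturbation-response scanning to separate effector from sensor
    residues.  On the sequence side it reads and weights family alignments,
    scores pairwise coevolution with five complementary statistics (MIp,
    OMES, SCA, mean-field direct information, and sparse inverse-covariance
    scoring), and synthesises them into consensus interdomain residue pairs
    and cumulative interdomain coevolution propensity profiles with
    structural contact annotation.  Ground-truth synthetic generators for
    two-domain bead structures and coupled alignments make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
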