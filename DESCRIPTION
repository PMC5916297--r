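Package: kelpconn
Title: Population Connectivity Inference for Kelp from Sequence and
    Microsatellite Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating genetic connectivity among kelp
    populations from a mitochondrial sequence locus and diploid
    microsatellite panels. Implements per-population diversity statistics
    (haplotype and nucleotide diversity with Nei standard errors),
    minimum spanning haplotype networks, distance-based AMOVA with
    permutation tests and Bonferroni-corrected pairwise structure,
    principal coordinates analysis, a structured-coalescent simulator
    under the isolation-with-migration model (finite-sites sequence and
    stepwise microsatellite mutation), rejection-ABC inference of
    demographic parameters, molecular-clock calibration arithmetic,
    forward-time island-model simulation of the approach to
    migration-drift equilibrium, and the comparison of equilibrium
    (Wright island model) against nonequilibrium (coalescent) migration
    estimates. A synthetic-data generator produces study-shaped datasets
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
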