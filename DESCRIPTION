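Package: breedsim
Title: Breeding-Scheme Simulation with Whole-Genome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates meiosis on a genetic linkage map (Poisson crossover
    counts with chromosome length in Morgans as the rate, uniform crossover
    placement, a 0.1-cM bin lattice) and couples the simulator to
    whole-genome prediction models (ridge/RR-BLUP, Bayesian lasso, extended
    Bayesian lasso, Bayes C, and RKHS kernel regression) so that recurrent
    genomic-selection breeding schemes can be simulated and genomic
    estimated breeding values tracked across generations. Also provides the
    supporting analyses such schemes rest on: marker quality filters,
    additive kinship, linkage disequilibrium, broad-sense heritability from
    replicated trials, mixed-linear-model and shrinkage-based association
    scans, and leave-one-out cross-validation of prediction accuracy,
    together with a synthetic-data generator that makes every analysis
    reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    data.table,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
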