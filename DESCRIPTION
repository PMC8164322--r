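Package: isthmusclock
Title: Neutral Substitution Rates from GBS Loci via Isolation-with-Migration Coalescent Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates genome-wide neutral substitution rates from
    reduced-representation (GBS/RADseq) locus alignments using a Bayesian
    isolation-with-migration multi-species coalescent model, calibrated by
    biogeographic vicariance (closure of the Isthmus of Panama). Provides a
    coalescent simulator for GBS data with restriction-site allelic dropout
    and depth-driven missingness, pyRAD-style locus filtering (paralog
    heuristics, minimum-individual and minimum-species dataset filters),
    locus-sharing bias diagnostics (presence-absence matrices, Jaccard
    distances, NMDS ordination, nested linear models), an MCMC sampler for
    divergence times, population sizes and migration rates on unphased
    genotypes, and conversion of mutation-scaled estimates to absolute
    rates, times and population sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    vegan,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
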