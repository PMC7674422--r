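Package: fossilcal
Title: Fossil-Calibrated Clade-Age Priors and Bayesian Node Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds clade-age calibration prior densities from fossil first
    occurrences under a birth-death diversification process with stochastic
    fossil sampling, including a weighted two-fossil mixture prior for clades
    whose first record is ambiguous. Provides a Metropolis-Hastings sampler
    over node ages on a fixed rooted topology that combines these calibration
    densities with a birth-death node-age prior and an optional strict-clock
    GTR+Gamma sequence likelihood, trace summaries (effective sample size,
    highest-posterior-density intervals), and a deterministic filter cascade
    for selecting phylogenomic markers from precomputed ortholog metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    Biostrings,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    coda,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
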