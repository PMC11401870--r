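Package: neutronDNA
Title: Neutron Radiation Damage Kinetics and Information-Loss Risk for DNA Data Storage
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the risk of information loss in dried DNA data storage
    pools due to atmospheric neutron radiation. Estimates per-nucleotide and
    per-water non-elastic neutron interaction cross sections by Monte Carlo
    impact sampling over stacked atomic structures, fits a piecewise
    cubic-in-log-energy cross-section model by Poisson regression, combines
    the fitted cross sections with a ground-level reference neutron flux
    spectrum through mass-action damage kinetics to obtain per-strand damage
    rates and half-lives, and propagates the per-strand hazard into a
    hypoexponential first-passage model for the expected time to data loss of
    a multi-copy oligonucleotide pool. Also provides the accompanying assay
    analyses: four-parameter logistic fits of qPCR amplification curves,
    per-base sequencing error rates from alignments, and linear-trend t
    tests against neutron fluence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    Biostrings,
    data.table,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Sequencing
RoxygenNote: 7.3.3
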