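Package: raftgen
Title: Comparative Population-Genetic Connectivity Analysis for Codominant Multiallelic Markers
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative population-genetic analyses of codominant
    multiallelic (microsatellite) genotype data from georeferenced sampling
    sites: Genepop and delimited-table input/output, no-admixture Bayesian
    cluster assignment of individuals to genetic species, Monte-Carlo
    Hardy-Weinberg diagnostics and EM estimation of null-allele frequencies
    with corrected allele frequencies, differentiation statistics (Jost's
    D with HWE-conditional bootstrap confidence intervals, Weir-Cockerham
    F_ST raw and null-corrected, Hedrick's standardized G''_ST, island-model
    migrant numbers), null-aware Cavalli-Sforza & Edwards chord distances,
    Mantel and partial Mantel permutation tests of isolation by distance and
    habitat discontinuity, spatial analysis of shared alleles (SAShA), a
    Balding-Nichols genotype simulator for calibration and power studies, and
    an end-to-end pipeline producing machine-readable study reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
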