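Package: fragdiv
Title: Genomic Erosion Analysis for Fragmented Bird Subpopulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify the genomic consequences of local population
    decline from sparse SNP-array genotypes: site-based heterozygosity,
    moment-based (F^III) and ROH-based (F_ROH) inbreeding coefficients,
    runs of homozygosity called both by PLINK-style sliding-window genotype
    counting and by a two-state hidden Markov model, method-of-moments
    pairwise identity-by-descent (Z0/Z1/Z2, PI_HAT) with pedigree-calibrated
    relationship classes, allele-frequency-drift diagnostics, a two-deme
    Wright-Fisher forward simulator with migration, and a pedigree
    gene-dropping simulator with recombination that provides exact
    autozygosity and kinship truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
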