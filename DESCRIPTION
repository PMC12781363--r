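Package: genodiv
Title: Genomic Diversity, Runs of Homozygosity and Selection Scans for
    SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for characterising genomic diversity and
    population structure in livestock populations genotyped on SNP arrays.
    Provides genotype input/output for VCF and PLINK text formats, a
    six-rule quality-control procedure with an exact Hardy-Weinberg test,
    per-population heterozygosity summaries, genomic relationship matrices
    and PCA, identity-by-state distances, sliding-window detection of runs
    of homozygosity (ROH) with ROH-island calling, ten genomic inbreeding
    coefficients (F_ROH and its length-stratified variants, F_GRM, F_HOM,
    F_UNI), linkage-disequilibrium decay and Sved-equation effective
    population size estimation, and windowed Weir-Cockerham F_ST selection
    scans.  A forward-in-time Wright-Fisher simulator with controllable
    inbreeding, planted autozygous tracts, sweeps, and population
    divergence supplies ground-truth data so that every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
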