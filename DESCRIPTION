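Package: rohscan
Title: Runs of Homozygosity, FST and Selection-Signature Scans for SNP-Array Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for within-breed selection-signature analysis on diploid
    autosomal SNP-array genotypes. Implements genotype input/output (PED/MAP
    and VCF), a quality-control cascade (sample and marker call rate, minor
    allele frequency, heterozygosity observed/expected ratio), consecutive-runs
    detection of runs of homozygosity (ROH) with length classification and
    genomic inbreeding coefficients (F_ROH), population-level ROH islands and
    consensus ROH clusters with case-control homozygosity association testing,
    per-marker Weir-Cockerham FST scans, genomic-relationship-matrix principal
    component analysis, morphometric trait statistics with Tukey compact letter
    displays, gene-interval annotation, and a Balding-Nichols genotype
    simulator that plants known autozygous segments so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    igraph,
    car,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
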