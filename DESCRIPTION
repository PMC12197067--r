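Package: clonemate
Title: Clone Detection, Diversity and Simulated-Cross Breeding-Pair Selection
    for Minimal Conservation Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for SNP genotype data from very small clonal
    plant collections managed for conservation. Reads DArT-style one-row SNP
    reports, plain genotype matrices and VCF; applies a recorded quality-control
    cascade (individual and locus call rate, reproducibility, read depth,
    monomorphic loci, secondaries); collapses ramets into multilocus genotypes
    (genets) by pairwise dissimilarity; computes observed and expected
    heterozygosity and inbreeding coefficients per management group; estimates
    pairwise Weir-Cockerham FST with equal-n subsampling; ordinates samples by
    principal coordinates analysis; excludes hybrid parentage by the
    opposing-homozygote rule; and ranks candidate breeding pairs by the mean
    observed heterozygosity of simulated Mendelian offspring. Includes a
    synthetic-data generator with known genet, pedigree and divergence truth
    so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
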