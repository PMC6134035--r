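Package: fragdiv
Title: Population-Genetic Analysis of Fragmented Tree Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying genetic diversity and demographic history in
    fragmented plant populations genotyped with marker sets of contrasting
    mutation rate (PCR microsatellites, RAD-mined microsatellites, and RAD
    transition/transversion SNPs). Provides readers and writers for Genepop,
    VCF and TSV genotype tables; a RAD-SSR genotype caller that mines
    di-nucleotide repeat loci from catalog consensus sequences and calls
    integer-coded alleles from read bundles under depth and fraction
    thresholds; diversity and differentiation statistics (rarefied allelic
    richness, expected heterozygosity, inbreeding coefficients,
    Weir-Cockerham F_ST, Mantel isolation-by-distance tests); a
    maximum-likelihood local F_ST estimator under the Balding-Nichols
    multinomial-Dirichlet model; linkage-disequilibrium effective-population-
    size estimation with sample-size bias correction; a multi-population
    coalescent simulator with stepwise microsatellite mutation; and
    approximate Bayesian computation for demographic scenario choice and
    parameter estimation, with posteriors combinable across marker sets. A
    synthetic-data module generates complete study fixtures (genotypes, read
    bundles, population metadata) so that every stage of the pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    geosphere,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
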