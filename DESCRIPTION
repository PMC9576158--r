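Package: wildcore
Title: SNP Diversity Analysis and Core-Collection Construction for Wild
    Rice Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for diploid biallelic SNP genotype panels of
    germplasm collections, modelled on common wild rice (Oryza rufipogon)
    surveys: locus filtering on minor allele frequency and call rate,
    per-population diversity statistics (MAF, Np, Na, Ne, Nei's unbiased
    diversity, Shannon-Wiener index, PIC, observed and expected
    heterozygosity), modified Rogers and Nei (1972) genetic distances,
    neighbour-joining trees, principal component analysis, and
    population-priority core-collection construction by greedy allele
    coverage and weighted-objective subset optimization, with core versus
    whole-collection retention reports. Includes an island-model
    (Balding-Nichols) genotype simulator with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    vcfR,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
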