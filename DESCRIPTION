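Package: erodescan
Title: Genome Erosion Scans from Resequencing Genotypes: Runs of
    Homozygosity, Inbreeding Age Decomposition and Mutational Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies genome erosion in small, fragmented populations from
    multi-sample genotype data. Implements site and genotype quality
    filtering, sliding-window detection of runs of homozygosity (ROH), the
    genomic inbreeding coefficient F_ROH with decomposition into coalescence
    age bins via g = 100/(2rL), genome-wide heterozygosity and a simplified
    maximum-likelihood estimator of per-site heterozygosity (theta) and
    sequencing error from read profiles, zygosity-stratified mutational-load
    proportions by variant impact class, population structure via the
    variance-standardized genomic relationship matrix with PCA, and
    Kruskal-Wallis plus Dunn post hoc group comparisons. Includes a synthetic
    diploid genotype simulator that plants identity-by-descent tracts of
    known age class and emits a truth ledger, so every stage has a recovery
    test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
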