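Package: taxadiag
Title: Species-Diagnostic SNP Mining and Admixture Profiling for
    Admixed Crop Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines species-diagnostic SNP markers for a set of ancestral
    taxa from diploid biallelic genotype matrices using a focal-taxon
    versus pooled-rest G_ST differentiation statistic, detects and masks
    interspecific introgression at the gene-fragment level before
    re-estimating ancestral allele frequencies, and profiles the admixture
    structure of test accessions from the zygosity of diagnostic alleles.
    Includes standard population-genetic summaries (observed and unbiased
    expected heterozygosity, Wright's fixation index, Weir-Cockerham
    F_ST, simple-matching dissimilarity, SNP density), principal
    coordinates and dosage PCA ordinations, and a pedigree-aware
    synthetic genotype simulator with truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
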