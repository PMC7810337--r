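Package: breedtrace
Title: Genomic Diversity and Breed Traceability from SNP Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for livestock breed-diversity studies based on
    medium-density SNP array genotypes: PLINK text and binary input/output
    with dataset merging and quality control; detection of runs of
    homozygosity (ROH) with the consecutive method, ROH length classes,
    shared ROH islands and the genomic inbreeding coefficient F_ROH;
    maximum-likelihood admixture with cross-validated selection of the
    number of ancestral populations; discriminant analysis of principal
    components (DAPC) for breed assignment under supervised,
    semi-supervised and leave-breed-out cross-validation; and a
    Balding-Nichols multi-breed genotype simulator with planted
    autozygosity and per-call missingness for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
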