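Package: episelect
Title: Methylation-Based Genotyping and Balancing-Selection Tests at
    CpG-Disrupting Variants
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain linking a methylation-disrupting SNP to signals
    of balancing selection. Provides beta/M-value transforms and genotype
    inference from the tripartite M-value distribution at a SNP-overlapping
    methylation probe (one-dimensional Gaussian mixture fitted by
    expectation-maximization), population allele and genotype frequency
    estimation with a Hardy-Weinberg chi-square test, extraction of variant
    sites from a multiple sequence alignment into a VCF-serializable table,
    Tajima's D with its full constant decomposition and minor-allele
    frequency filtering, and a synthetic-data generator (Gaussian
    methylation classes, inbreeding-parameterized genotype counts, neutral
    and two-class balanced coalescent haplotype samples) so the whole
    pipeline is testable without access to the original placental cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    VariantAnnotation,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
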