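Package: poolpg
Title: Population Genomics from Pooled Metagenome Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes within-sample nucleotide diversity, pairwise fixation
    index (FST) at genome and gene level (nucleotide and amino-acid),
    gene-wise pN/pS with Nei-Gojobori site counting, per-codon amino-acid
    frequencies, and a locus-shuffling permutation test for gene-wise
    differentiation, from multi-sample VCF files of pooled (metagenome)
    variant calls against a reference genome. Includes per-sample minimum
    read-count filtering, without-replacement subsampling of allele counts
    to a fixed depth, and a synthetic-data generator (Balding-Nichols
    population frequencies, binomial read sampling) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    vcfR,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
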