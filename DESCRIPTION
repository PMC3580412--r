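Package: somaticmate
Title: Somatic Alteration Calling from Tumor/Normal Mate-Pair Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, tested re-implementation of a matched tumor/normal
    whole-genome somatic-alteration analysis for long-insert (1.5 kb) mate-pair
    libraries with short (50 bp) reads. Provides a stranded
    Kolmogorov-Smirnov-distance genotyper, a strand-minimum two-proportion
    somatic SNV caller with strict/lenient consensus, two-step somatic indel
    filtering against a germline window, binned log2-ratio copy-number
    segmentation with zygosity states, discordant mate-pair translocation
    detection with chromosome-wise outlier cutoffs and germline subtraction,
    and summary/validation arithmetic (Ti/Tv, variant-class accounting,
    clonal coverage, delta-delta-Ct qPCR fold changes). A paired tumor/germline
    mate-pair simulator with a known truth set (read-level and Poisson
    depth-level modes, configurable tumor purity) supports validation of every
    caller against planted events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
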