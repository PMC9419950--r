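Package: AmpliCas
Title: Quantification of CRISPR-Cas9 Editing from Amplicon Sequencing and
    Design of Guide-Complementary Oligonucleotide Inhibitors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying Cas9-induced insertions and deletions from
    barcoded paired-end amplicon sequencing: read-pair merging, inline-barcode
    demultiplexing with primer-structure filtering, fit alignment of reads to
    pooled amplicon references, CIGAR-based indel calling, per-locus editing
    frequencies, and an on-target specificity statistic. Includes a designer
    for guide-complementary DNA oligonucleotide inhibitors (length variants,
    PAM-loop fold-back variants, and scrambled controls), a ground-truth
    synthetic read simulator for end-to-end validation, gel-densitometry
    digestion quantification, and the Shapiro-Wilk/Levene/ANOVA/Tukey
    statistical chain for replicate comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    Rcpp,
    car,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
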