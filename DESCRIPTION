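Package: ripclass
Title: Classifying Direct Nonsense-Mediated Decay Substrates from RNA-seq and RIP-seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Count-based discovery of direct substrates of nonsense-mediated
    mRNA decay (NMD) from paired RNA-seq and UPF1/SMG-2 RIP-seq experiments
    across NMD-proficient and NMD-deficient genotypes. Builds intron-only
    feature catalogs by merging each gene's exons, counts spliced reads
    against gene or intron features in union mode, filters on counts per
    million, performs two-group negative-binomial differential abundance
    tests with trimmed-mean-of-M-values normalization, conditional-likelihood
    dispersion estimation and Benjamini-Hochberg correction, and combines
    three comparisons (mutant vs wild-type input, IP vs input, IP vs control
    IP) into a Class I-IV substrate classification at gene and intron level.
    Includes over-representation tests for gene families and a synthetic-data
    generator emulating the six-condition design for end-to-end validation
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
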