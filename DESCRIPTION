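Package: zfarray
Title: Zinc-Finger Minisatellite Decomposition and Codon Site-Model
    Tests of Positive Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising C2H2 zinc-finger (ZF) minisatellite
    arrays such as the PRDM9/PRDM7 DNA-binding domain in ruminants.
    Decomposes ZF-domain exon amplicons into a conserved leading finger
    plus tandem 84-bp repeat units, catalogues and codes the distinct
    28-amino-acid domains across species, types repeat-count alleles
    (A-G for 6-12 fingers), screens paralogous copies for pseudogenising
    lesions (premature stop codons, frameshifts), and tests the coding
    units for positive selection with Goldman-Yang codon site models
    (M0, M1a, M2a, M7, M8) under F3X4 frequencies: Felsenstein pruning
    likelihoods, likelihood-ratio tests, and Bayes empirical Bayes
    identification of positively selected sites mapped to the
    DNA-contact helix positions (-9, -5, -2, -1, 2, 3, 6). Includes a
    synthetic-data generator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
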