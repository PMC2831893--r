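Package: retroclade
Title: Clade-Partitioned Codon Models and Retrocopy Locus Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of nonsynonymous/synonymous rate
    ratios (dN/dS, omega) under a time-continuous Markov codon substitution
    model with branch partitions, so that a foreground clade (for example a
    recently emerged retrogene family) carries its own omega distinct from the
    background. Provides Felsenstein-pruning likelihoods, one-ratio (M0) and
    two-clades model fits with standard errors and the nested likelihood-ratio
    test, an exact event-by-event codon sequence simulator with
    retrotransposition/duplication scenarios and an optional CpG-deamination
    mutation bias, maximum-parsimony ancestral codon reconstruction with
    substitution classification and CpG annotation, and retrocopy
    insertion-locus diagnostics: in-silico PCR, IUPAC restriction digest,
    target-site-duplication detection, L1 endonuclease site scanning, and
    protein difference mapping onto Ras-family GTPase motifs.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
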