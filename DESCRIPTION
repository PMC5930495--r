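Package: cdur
Title: Cytidine Deaminase Under-Representation Reporter
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides whether a protein-coding nucleotide sequence is under-
    or over-represented for AID/APOBEC cytidine-deaminase mutation motifs
    (TC, WRC, SYC, CCC and friends). The observed motif count, the number of
    nonsynonymous C-to-T transitions at motif cytidines, and their ratio are
    compared against empirical null distributions built from synonymous
    codon shuffles of the same sequence under three constraint-preserving
    schemes: gc3 (corrects for third-position GC content), n3 (preserves
    base composition exactly via within-class permutation), and dn23
    (preserves positions-2-3 dinucleotide frequencies). Reports empirical
    under-representation p-values, null summaries, pairwise motif
    correlations and bivariate-normal conditional p-values, plus a
    synthetic-CDS simulator for building positive and negative controls.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
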