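Package: ccchfamily
Title: Identification and Characterization of CCCH-Type Zinc Finger Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcriptome- or proteome-wide characterization of
    CCCH-type zinc finger (C3H) protein families. Scans protein sequences for
    CCCH zinc finger motifs (C-Xa-C-Xb-C-Xc-H) under configurable spacing
    bounds, classifies motif subtypes and tabulates a family-wide census,
    detects tandem zinc finger (TZF) architectures including the plant-specific
    arginine-rich RR-TZF arrangement, scans for the leucine-rich nuclear export
    signal consensus, deduplicates near-identical sequences by global-alignment
    identity, computes molecular weight and isoelectric point profiles, and
    implements qPCR 2^(-ddCt) relative expression and log2-FPKM row-scaling
    transforms. A seeded synthetic-sequence generator plants motifs, cassettes
    and signals with a machine-readable truth table so every pipeline stage can
    be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
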