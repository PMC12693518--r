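Package: bermass
Title: Mass-Labeled Probe Analysis of Base Excision Repair Patch Sizes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the isotope-labeled plasmid probe assay that reads out
    base excision repair (BER) synthesis tract lengths by mass spectrometry.
    The package models mass-labeled probe substrates and their in silico
    restriction digestion, computes oligonucleotide elemental compositions and
    neutral masses including fully 13C/15N-substituted residues, enumerates
    the theoretical mass ladder of repair outcomes (patch sizes and 5'
    excision classes), deconvolves negative-mode ESI spectra and quantifies
    per-class product proportions from peak heights, and analyzes replicate
    proportion tables with Dirichlet regression, likelihood-ratio tests,
    per-component beta regression and Benjamini-Hochberg FDR control. A
    seeded simulator generates compliant probe sequences, synthetic spectra
    and replicate composition tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'bermass-package.R'
    'AllClasses.R'
    'enzymes.R'
    'mass-engine.R'
    'probe-model.R'
    'product-space.R'
    'spectrum-pipeline.R'
    'compositional-stats.R'
    'synthetic-data.R'
    'io.R'
    'cli.R'
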