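Package: transmut
Title: Mapping and Characterizing Trans-Regulatory Mutations from Bulk
    Segregant Sequencing and Plate-Based Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for identifying trans-regulatory mutations
    affecting a focal gene's expression in yeast mutagenesis screens.
    Implements freebayes-dialect variant filtering and annotation, per-variant
    likelihood-ratio (G) tests on bulk-segregant allele counts with signed
    association calls, aneuploidy detection from coverage ratios, linkage
    grouping and a parametric bootstrap for disambiguating linked candidates,
    the two-level permutation test that accounts for nested plate position
    variance in flow-cytometry expression data, mutation-spectrum and
    enrichment statistics contrasting regulatory and non-regulatory mutation
    sets, transcription-factor network inference from binding and expression
    evidence matrices, competitive-fitness estimation from two-fluorophore
    competition counts, and expected mutation loads for error-prone PCR.
    A seeded synthetic-data generator emulates every input (EMS mutation
    cohorts, meiotic crosses with truncation-selected bulks, 96-well plate
    expression data with position effects, and competition assays) so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
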