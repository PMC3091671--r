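Package: rrlSNP
Title: Reference-Free SNP Discovery from Multi-Tier Reduced Representation Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reference-free pipeline for single nucleotide
    polymorphism (SNP) discovery between two inbred genotypes using a
    multi-tier reduced representation library (mtRRL) design: in-silico
    restriction digestion with two-tier gel size selection, simulation of
    long (454-style) and short (Genome Analyzer-style) sequencing reads,
    construction of a long-read reference set with quality masking and
    organellar screening, ungapped short-read alignment with depth- and
    quality-thresholded biallelic SNP calling, an ordered five-stage
    false-positive filter cascade (paralog self-mapping, allele-swap
    verification, repeat and contaminant screens, allele-consistency
    screen), and flanking-sequence extraction with a transparent assay
    designability heuristic and an e-PCR style primer specificity screen.
    Includes a synthetic two-genotype genome generator with planted truth
    tables for validation-rate and recall evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
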