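Package: covmark
Title: Coverage-Asymmetry Discovery of Species-Diagnostic Genomic Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Alignment- and k-mer-based discovery of candidate diagnostic
    nuclear markers between closely related genomes. Provides a seeded
    synthetic-data generator (genome pairs with divergent islands,
    species-specific insertions and sex-enriched repeat families, plus
    paired-end read simulation), a minimal verifiable seed-and-extend read
    mapper with SAM input/output, per-base depth and coverage-breadth
    statistics with mapping-quality sweeps, zero-coverage interval
    extraction, sex depth-ratio screening, sex-specific k-mer set
    subtraction with copy-number windows, de novo assembly of unmapped
    read pairs with reciprocal validation, in-silico PCR specificity
    checks, MinHash bottom-sketching with Mash distances, and principal
    coordinates ordination, orchestrated by a deterministic pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
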