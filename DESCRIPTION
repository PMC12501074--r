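Package: craci
Title: Quantitative Dihydrouridine Site Calling from Misincorporation Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Base-resolution detection and quantification of dihydrouridine (D)
    from the T-to-C misincorporation signatures produced by chemical-reduction
    sequencing libraries (CRACI). Provides per-motif linear calibration of
    mutation ratio to D stoichiometry from 6-level D-mixture probe series,
    multi-criteria site callers for ncRNA (treated/input libraries) and for
    mRNA against an in-vitro-transcribed background (replicate t-test, fold
    changes, tRNA-region exclusion, binomial test), condition-comparison
    statistics for writer-enzyme assignment, a seeded synthetic count
    simulator, and readers/writers for count tables, SAM pileups, FASTA, BED
    and call tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
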