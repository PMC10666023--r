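Package: dsbend
Title: Strand-Specific Mapping and Resection Analysis of Meiotic DSB Ends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for strand-specific sequencing of resected
    meiotic double-strand-break (DSB) ends: RPM-normalized strand coverage
    tracks, Hann-smoothed hotspot-centered co-oriented average profiles,
    resection-length distribution estimation with background subtraction and
    core exclusion, Poisson-window DSB peak calling with Benjamini-Hochberg
    correction, peak/hotspot-class overlap accounting, pseudoautosomal-region
    signal summaries, and exact binomial proportion summaries. Includes a
    seeded generator of synthetic resected-DSB end reads with genotype
    presets so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
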