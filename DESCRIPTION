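Package: sweepmeta
Title: Meta-Assembly of Selection Signatures from Published Genome Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines heterogeneous published selection-signature scan
    results across studies and populations into meta-selection-scores
    (MSS). Per-study contributions are down-weighted for repeated DNA
    samples across studies (DNA score) and standardised for the
    significance threshold at which each result set was declared (SNP
    score tiers for the top 5%, 1% and 0.1%). Windowed MSS profiles are
    computed at every reported locus, validated peaks (MSS > 3) are
    called, merged peaks are split at intervening valleys, and regions
    are classified as unique to one population or shared across
    populations. Includes marker-anchored coordinate harmonisation
    between genome assemblies, gene-density annotation, a synthetic
    multi-study corpus generator with planted hotspots for method
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
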