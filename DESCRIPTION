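Package: oakpine
Title: Multiscale Caching Trees for Genome-Browser Track Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Client-side caching machinery for genome-browser style track
    display. Sparse tracks (BED) are cached in Oak, a weight-balanced
    key/value tree with placeholder keys marking unloaded genome; dense
    signal tracks (bedGraph) are cached in Pine, a fixed-branching
    multiscale tree of region summaries (bases, sum, sum of squares,
    max, min) built to the depth the screen resolution requires. A
    session engine turns view queries into minimal backend fetches,
    meters every simulated transfer in a ledger, and evicts data
    untouched for ten queries ("withering"). Payloads render to static
    SVG, including a double-layer panel that links paired genomic
    intervals (Hi-C style interactions) between two independently
    scrolled coordinate axes on a red-to-green intensity scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    IRanges,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
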