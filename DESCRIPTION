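Package: pacsites
Title: Discovery of Phage Packaging Initiation Sites from Read Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects bacteriophage packaging initiation sites (pseudo-pac
    sites) in host bacterial genomes from the coverage of phage-derived
    sequencing reads. Headful-packaging phages such as P22 occasionally
    initiate packaging at host sequences resembling their pac site, which
    produces characteristic sharp jumps in read coverage followed by
    strand-directional, stair-like decay. The package detects these jumps,
    extracts the best pac-consensus match in the surrounding window, builds
    a degenerate (bracket-style) consensus from the candidates, scans
    genomes on both strands for further matches, and classifies matches by
    coverage support. A headful-packaging coverage simulator with planted
    sites makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
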