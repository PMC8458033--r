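Package: ffpekit
Title: Simulation and Filtration of Artifact Chimeric Reads in FFPE Sequencing Data
Version: 0.1.0
Authors@R:
    person("ffpekit", "developers", email = "ffpekit@example.org", role = c("aut", "cre"))
Description: Formalin fixation denatures DNA and enriches single-stranded
    fragments that re-anneal at short reverse complementary (SRC) regions,
    producing artifact chimeric fragments whose reads mimic split-read
    support for structural variants. ffpekit provides a read simulator that
    generates realistic FFPE-style artifact chimeric reads alongside normal
    reads (positional Phred profiles, lognormal SRC lengths and adjacent
    distances, beta-distributed distant-read spikes), a structural-variant
    spiker that plants non-overlapping DEL/DUP/INV/TRA events with a
    machine-readable truth table, an idealized split-read aligner for
    desk-scale testing, a two-step filtration algorithm that removes
    artifact chimeric reads from coordinate-sorted BAM files while
    preserving split reads from true structural variants, and evaluation
    utilities (read-level purity/recall, breakpoint matching at a
    configurable tolerance with PPV/sensitivity/F1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    S4Vectors,
    data.table,
    stringi,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
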