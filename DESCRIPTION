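Package: ampliMeth
Title: Targeted Amplicon Bisulfite Sequencing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of targeted amplicon bisulfite sequencing data from raw
    single-end reads to per-CpG methylation tables. Provides target-region
    parsing with CpG enumeration, per-read 3' quality clipping and length
    filtering, a self-contained three-letter (converted-space) semi-global
    aligner for directional and non-directional libraries, per-CpG methylation
    calling with strand-specific and CpH side channels, coverage- and
    strand-based call filtering, read-level methylation-pattern (epiallele)
    extraction and cross-sample comparison, lollipop visualizations, and a
    synthetic bisulfite read simulator with known truth for validating every
    stage of the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
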