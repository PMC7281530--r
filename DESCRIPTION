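Package: poolscreen
Title: Pooled shRNA Drop-Out Screen Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of pooled shRNA drop-out (viability)
    screens read out by amplicon sequencing. Generates synthetic hairpin
    libraries, skewed abundance profiles, barcoded amplicon reads and
    count matrices with planted treatment effects; demultiplexes reads
    and counts hairpins into a hairpin-by-sample count matrix; simulates
    multinomial sampling to quantify how sampling error varies with
    hairpin abundance; normalises counts, filters low-abundance hairpins
    and calls depleted, enriched and lost hairpins per drug with
    cross-drug overlaps; and fits four-parameter Hill dose-response
    curves, extracts ECx doses, and scores drug-combination dose
    matrices with the zero-interaction-potency (ZIP) synergy model
    including overall and most-synergistic-area summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
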