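Package: peakconcord
Title: Signal-Stratified Concordance Analysis of ChIP-Seq Peak Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies positional and signal-level agreement between two
    databases of transcription factor binding sites distributed as BED
    narrowPeak files. Peaks are reduced to fixed summit windows, merged
    within each database, and compared by base-pair Jaccard indices and
    the Alroy-corrected Forbes coefficient. Regions are rank-binned into
    low/medium/high signal tiers and joined by genomic overlap to test
    whether high-signal binding sites preferentially co-occur across
    databases, with conditional bin distributions, recall and size-ratio
    summaries, and overlap fractions against high-occupancy-target (HOT)
    regions. A seeded synthetic generator produces paired pseudo-database
    fixtures with planted cross-database structure so the whole pipeline
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
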