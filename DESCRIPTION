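Package: poremodel
Title: De Novo K-Mer Pore Models from Basecaller Move Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds lightweight de novo k-mer current-level models ("pore
    models") for nanopore sequencing from crude signal-to-sequence alignments
    such as basecaller move tables. Raw current traces are converted to
    picoamps, normalized by median/median-absolute-deviation scaling, cut
    into per-k-mer events along a run-length encoded signal-to-sequence
    alignment ("ss" format), filtered by dwell time and event stability, and
    summarised into a k-mer level table. Includes detection of the base
    positions within a k-mer that drive the current level (so large models
    can be collapsed to lightweight ones over the significant positions),
    model-to-model Pearson comparison, a tolerance-based signal-point F1
    metric for alignment evaluation, and a signal simulator that generates
    reads with exact ground-truth alignments from a known model so the whole
    pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
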