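Package: telotiming
Title: Stochastic S-Phase Simulation and Telomere Replication-Timing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for copy-number-based replication-timing analysis of
    budding-yeast genomes and for quantitative telomere biology readouts.
    Includes a stochastic origin-firing S-phase simulator that generates
    per-bin read counts, flow-cytometry DNA-content time courses, sonication
    fragment-length distributions, per-telomere TG-tract lengths and paired
    ChIP/input signals; Gompertz fitting of percent-bulk-replication time
    courses; relative copy-number profiles on the 1x-2x scale from
    replicating versus non-replicating samples; efficiency-aware ChIP-qPCR
    and dot-blot percent-input quantification with telomere-length
    correction and a sonication co-fragmentation bias model; and terminal
    restriction fragment analysis with in-silico Southern lanes and strain
    comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    yaml
Suggests:
    BiocGenerics,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
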