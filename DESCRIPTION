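Package: methconcur
Title: Read-Level Methylation Concurrence Analysis for Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the concurrence of active DNA methylation and
    demethylation on single molecules from read-level bisulfite sequencing
    data. Reads are dissected into methylated, unmethylated and
    methylation-concurrence fragments, from which the methylation
    concurrence ratio is computed per CpG or per region, alongside
    companion metrics (traditional mean methylation, CHALM, Shannon
    entropy, Epipolymorphism, PDR). Includes the DNMT-TET joint regulation
    score for promoter co-occupancy, a replicate-free differential
    procedure based on a half-normal local false discovery rate,
    undermethylated-region and methylation-canyon calling with
    background-distribution thresholding (Cramer-von Mises model
    selection), canyon annotation statistics, a synthetic epiread
    generator with closed-form ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fitdistrplus,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
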