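Package: cnaprep
Title: Preprocessing, GC Normalization and Copy-Number Calling for
    Windowed Sequencing Read Counts
Version: 0.1.0
Authors@R:
    person("cnaprep", "developers", email = "cnaprep@example.org",
           role = c("aut", "cre"))
Description: Windowed read-count preprocessing for somatic copy-number
    analysis of high-throughput sequencing cancer data. Summarizes SAM
    alignments into fixed-width window read-count profiles with
    paired-end read classification, applies five independent window
    filters (improper-read proportion, mean mapping quality, runs-test
    based automatic trimming with prior GC correction, common-CNV
    overlap, mappability), corrects GC-content bias with a two-pass
    segment-wise local regression ("seqnorm") that is robust to
    correlation between GC content and copy number, segments the
    normalized profile with penalized least-squares changepoints, and
    calls integer copy numbers from explicit thresholds. Includes a
    synthetic-data generator with known truth for end-to-end testing.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
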