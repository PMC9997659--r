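Package: spliceforce
Title: Differential Splice-Junction Analysis, Cassette-Exon PSI, and
    Force-Ramp Unfolding-Step Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to discover and characterize non-annotated cassette
    exons from splice-junction read counts: STAR SJ.out.tab ingestion,
    gene annotation and novel-junction classification, differential
    junction expression with observation-level variance weights and
    empirical-Bayes moderated t-statistics, percent-spliced-in (PSI)
    quantification from inclusion/skipping junction trios, biweight
    midcorrelation of junction or event profiles with continuous sample
    traits, hypergeometric over-representation of ranked correlates,
    in-silico RT-PCR amplicon sizing with in-frame insert translation,
    and single-molecule force-ramp trace analysis (change-point
    unfolding-step detection, unfolding-force histograms). Includes
    seeded synthetic-data generators for junction cohorts carrying
    hidden cassette exons, coupled traits, PCR template fixtures, and
    Bell-Evans force-ramp bead traces, plus a reproducible end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
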