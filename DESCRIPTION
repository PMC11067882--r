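Package: tfscreen
Title: Pooled Transcription-Factor Overexpression Screen Analysis for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pooled induced transcription factor (iTF)
    overexpression screens read out by droplet single-cell RNA-seq.
    Builds unique vector-ORF junction tags that distinguish ectopic
    transcripts from their endogenous counterparts, scans reads for those
    tags, aggregates tag hits to UMI (transcript) level, assigns each cell
    its induced factor via a minimum-UMI threshold sweep, and quantifies
    each factor's cell-fate-conversion potential with a differentiation
    index: the z-normalised Euclidean distance of each cell from the
    control-cell centroid in principal-component space. Includes
    gene-set-restricted index variants, Mann-Whitney potency tests with
    multiple-testing correction, percentile ranks, TF similarity
    clustering, pseudobulk summaries, moving-window smoothing, and seeded
    synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    Matrix,
    data.table,
    fgsea,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
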