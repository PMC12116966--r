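Package: m6akit
Title: MeRIP-Seq Peak Calling, Spike-In Anchored mRNA Decay Kinetics and
    Time-Course Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the transcriptome-level analysis of N6-methyladenosine
    (m6A) regulation during cell-state transitions: sliding-window m6A
    peak calling from paired MeRIP-seq IP/input coverage (RPKM-normalized
    windows, fold-enrichment thresholding, merging of adjacent enriched
    windows), mRNA half-life estimation from actinomycin-D time courses with
    ERCC spike-in size factors and RUV-style removal of unwanted variation,
    time-course differential-expression classification and set overlaps,
    fuzzy c-means clustering of standardized temporal profiles,
    hypergeometric over-representation analysis against GMT gene-set
    collections, and m6A-ELISA standard-curve quantification. Includes
    ground-truthed synthetic-data generators for counts, decay time courses
    and IP/input coverage so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
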