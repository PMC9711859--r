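Package: aegrn
Title: Active-Edge Gene Regulatory Network Analysis of Retinoid-Driven
    Neuronal Specialization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs and interrogates signed transcription-factor to
    target-gene regulatory networks from temporal differential-expression
    data, as used to dissect retinoid-receptor-driven neuronal
    specialization of pluripotent stem cells. Provides trichotomous
    fold-change differential-expression calling, temporal co-expression
    path stratification, hierarchical cell-type marker annotation,
    sign-coherent "active edge" scoring of network edges, derivation of
    condition-specific and inhibited regulatory programs by set algebra
    over active-edge sets, promoter chromatin-state classification
    (H3K4me3/H3K27me3/FAIRE/RNAPII), and master-regulator ranking by
    simulated transcription-regulatory cascades against a
    degree-preserving randomized-network null. Includes a seeded
    synthetic-data generator that plants known master regulators,
    programs, and promoter states so that every stage of the pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
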