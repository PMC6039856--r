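Package: mlmescreen
Title: Identification of Telomerase-Positive Multi-Lineage-Marker-Expressing
    Cells in Single-Cell Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening single-cell expression profiles of
    preimplantation embryos for telomerase-positive cells that co-express
    markers of all three blastocyst lineages (epiblast, primitive endoderm,
    trophectoderm). Implements median-threshold digital marker calling, the
    multi-lineage markers-expressing (MLME) classification rule with
    hypergeometric enrichment statistics, HPAT lincRNA phenotype segregation,
    log-ratio gene-signature derivation with per-cell correlation scoring and
    rank-sum refinement, cross-dataset consensus signatures with
    maternal/embryonic origin summaries, an eigenvalue-entropy iterative
    gene filter for heatmap preparation, per-stage emergence-timeline
    estimation, and a seeded synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
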