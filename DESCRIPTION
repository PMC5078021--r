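Package: tlsea
Title: Two-Layer Similarity Ensemble Statistics for Phenotype Target Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the association between the active-compound set of a
    phenotypic screen (e.g. a cancer cell line) and the ligand set of each
    protein in a bioactivity database, using a two-layer similarity ensemble
    statistic over ECFP4/Tanimoto similarity matrices. The first layer gives
    an empirical significance (P_Z) for every phenotype compound against a
    protein's ligand set; the second layer aggregates standardized scores
    into a per-protein association score (P_O) against a random-set null.
    Includes activity and physicochemical filtering of compound libraries,
    background-model fitting of the random initial-score distribution,
    thresholded bipartite chemical-protein network export (SIF/GraphML), and
    synthetic-fixture generators with planted ground truth for calibration
    and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    igraph,
    ChemmineR,
    ChemmineOB,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
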