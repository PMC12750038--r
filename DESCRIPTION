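Package: ligassess
Title: Assessment of Protein-Ligand Pose and Affinity Predictions
Version: 0.1.0
Authors@R:
    person("CADD", "Assessment Toolkit", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for assessing blind predictions of protein-ligand
    binding poses and affinities, as run in community docking challenges.
    Implements binding-site superposed, symmetry-corrected ligand RMSD
    (BiSyRMSD), the local distance difference test for protein-ligand
    interactions (LDDT-PLI) with a false-contact penalty, binding-site
    accuracy metrics (BB-RMSD, LDDT-LP), skip-penalized group rankings,
    Kendall tau affinity-ranking statistics with a resampling-based
    experimental-noise ceiling, reliability-score (LScore) evaluation,
    and a SuCOS-style template-similarity score.  A synthetic-data module
    generates miniature reference complexes, perturbed predictions,
    multi-group submission cohorts, and affinity datasets with known
    ground truth so every stage of the pipeline can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
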