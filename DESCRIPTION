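Package: funnelscreen
Title: Multi-Stage Virtual-Screening Funnel Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the decision analytics of a multi-stage virtual
    screening campaign: curation of half-maximal inhibitory concentration
    (IC50) records into pIC50 modelling tables, correlation-based feature
    selection over binary molecular fingerprints, a pluggable regression
    harness with cross-validated and external validation, the full suite of
    external-validation statistics (Golbraikh-Tropsha regression-through-
    origin criteria, concordance correlation coefficient, QF1/QF2/QF3
    functions, rm2 metrics), screening enrichment and Z-normalised consensus
    scoring, rule-based negative design (substructure alerts, property
    windows, annotation thresholds), and molecular-dynamics trajectory
    stability analytics (superposition RMSD, radius of gyration, RMSF,
    hydrogen-bond occupancy, principal component analysis and free-energy
    landscapes). Synthetic-data generators with planted signal provide
    controlled substrates for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    e1071,
    nnet,
    kernlab,
    xgboost,
    ChemmineOB
Config/testthat/edition: 3
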