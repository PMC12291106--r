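Package: molrules
Title: Interpretable Substructure-Rule Mining for Small Molecular Activity Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Mines and validates interpretable structure-activity rules for
    small datasets of molecular modifiers (carboxylic acids grafted onto a
    metal-organic-layer catalyst). Declarative substructure rules written as
    SMARTS predicates are compiled into ternary {-1, 0, 1} feature matrices,
    scored with association statistics (support, confidence, lift, leverage),
    and validated with small-sample cross-validation designs (leave-one-out,
    balanced leave-P-out, forward selection, recursive feature elimination)
    on extremely randomised tree ensembles. An iterative multi-role refinement
    loop with a pluggable (scripted or live) chat backend automates rule
    proposal, criticism and revision; a synthetic-data generator plants known
    substructure rules so every stage can be tested against ground truth.
    Fragment-pooled physicochemical descriptors (PEOE charge, LogP, MR,
    LabuteASA, TPSA averaged over bond-radius shells around the carboxylate
    anchor) provide a traditional-descriptor baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    pROC,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
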