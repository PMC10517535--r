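Package: ecbscreen
Title: Iterative Evolutionary Chemical Binding Similarity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Similarity learning over chemical pairs for ligand-based virtual
    screening. Trains random-forest classifiers on evolutionarily related
    chemical pairs (compounds binding common or family-related protein
    targets), retrains them with experimentally derived pairing schemes
    (PP/NP/NN/PN) built from new active and inactive compounds, evaluates
    models by compound-level cross-validation with a common pair test set and
    precision-recall AUC, and screens chemical libraries with max-score
    aggregation, structural-novelty filtering, Butina clustering and
    cluster-center selection. Includes a synthetic-data generator producing
    scaffold-structured actives, random decoys and near-miss inactives so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    ranger,
    ChemmineR,
    ChemmineOB,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
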