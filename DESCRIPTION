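Package: pocketgcn
Title: Docking-Free Protein-Ligand Interaction Prediction with Pocket and
    Ligand Graph Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-ligand binding from a receptor pocket and a
    ligand SMILES string without docking. The binding pocket is represented
    as a residue-contact graph whose nodes carry 30-dimensional molecular
    vectors obtained by summing pre-trained circular-substructure
    embeddings of each amino acid (a mol2vec-style scheme), and the ligand
    as an atom/bond graph with GraphDTA-style atom features. Both graphs
    feed a two-branch graph convolutional network with either a sigmoid
    head for binder classification or a linear head for pKa affinity
    regression. Includes the data pipeline (pKa conversion from Ki/Kd/IC50,
    cross-combination negatives, pair-disjoint splits, class balancing), a
    full evaluation suite (AUC, TPR, precision, accuracy, MCC, RMSE, MSE,
    Pearson, Spearman, concordance index), a virtual-screening workflow
    with fingerprint Ward clustering of candidates, and a synthetic-fixture
    generator with a planted, learnable pocket-ligand compatibility signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    bio3d,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
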