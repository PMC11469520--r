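Package: apopharm
Title: Ligand-Free Pharmacophore Elucidation with Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proposing pharmacophore models directly from a protein
    binding site, without a bound ligand. A trainable multilabel site predictor
    scores candidate interaction points on a voxelized representation of the
    pocket; dense confidence grids are reduced to discrete typed feature points
    by connected-component analysis, complementary-group filtering and
    agglomerative clustering; a Pharmit-compatible geometric matcher screens
    active/decoy libraries to compute F1 and enrichment; and a deep Q-learning
    agent assembles an optimal feature subset by growing a heterogeneous
    protein-pharmacophore graph, scored by an SE(3)-invariant graph value
    network. Synthetic pocket, confidence-field and library generators with
    planted ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
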