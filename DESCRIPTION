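Package: pharmscreen
Title: Ligand-Based Pharmacophore Modeling, Activity Prediction, and
    Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ligand-based three-dimensional pharmacophore analysis:
    perception of chemical features (hydrogen-bond acceptors and donors,
    hydrophobes, aromatic rings) on 3D conformers, sphere-constraint
    pharmacophore models with Catalyst-style quadratic fit scoring,
    quantitative (HypoGen-style) calibration of a log-linear fit-to-IC50
    mapping with error factors and activity-scale classification,
    common-feature (HipHop-style) model generation by clique detection,
    validation by decoy-set retrieval statistics (enrichment factor,
    Guner-Henry score) and Fischer randomization, drug-likeness and ADMET
    filtering, Tanimoto similarity search, and a multi-stage virtual
    screening cascade with per-stage accounting.  A synthetic-data module
    generates molecules with planted pharmacophore geometry and activities
    following a known fit-to-IC50 law so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
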