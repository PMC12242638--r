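Package: phorescreen
Title: Pharmacophore-Constrained Virtual Screening for Kinase Inhibitor Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ligand-based and structure-informed virtual-screening toolkit
    for ATP-competitive kinase inhibitors, built around Rho-associated kinase
    (ROCK1/ROCK2) as the worked target. Provides bioactivity curation from
    ChEMBL-style exports (Ki/Kd activity classes, salt stripping, stereocentre
    and molecular-weight filters, Tanimoto diversity selection), circular
    (ECFP-style) fingerprinting with PCA/MDS chemical-space embedding and
    silhouette-selected clustering, consensus pharmacophore elucidation from
    overlaid ligands, geometric pharmacophore matching by correspondence
    search and Kabsch superposition, ROC/AUC and enrichment-factor protocol
    validation, and protein binding-site comparison (residue identity, Kabsch
    RMSD, Shrake-Rupley solvent-accessible surface area). Ships the published
    four-point ROCK1/ROCK2 pharmacophore models and synthetic-data generators
    with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    bio3d,
    cluster,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
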