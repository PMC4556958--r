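Package: combipharm
Title: Combinatorial Pharmacophore Modeling for Transporter Inhibitor
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based combinatorial pharmacophore (CP) modeling for
    classifying transporter inhibitors. Perceives six-type pharmacophore
    features (acceptor, donor, hydrophobe, negative, positive, aromatic
    ring) on 3D conformers, generates common 3- and 4-site hypotheses
    from active ligands by inter-site distance binning, scores them by
    survival, survival-inactive and selectivity, exhaustively enumerates
    3- and 4-member hypothesis combinations, selects the combination
    with the highest balanced accuracy on a labeled calibration set, and
    classifies ligands by the union rule (a ligand is predicted active
    if it matches any member hypothesis). Ships a deterministic
    synthetic-data generator that plants known pharmacophore geometries
    in feature-cloud libraries so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
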