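Package: skullmech
Title: Integrated Skull Morphometrics, Jaw Lever Mechanics, Planar Finite
    Elements, and Phylogenetic Comparative Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An integrated, testable pipeline for morphofunctional analysis
    of lateral-view skulls: TPS landmark input with scale calibration,
    generalized Procrustes superimposition, shape principal component
    analysis, centroid size and Tukey-fence outlier tests, jaw-closing
    mechanical advantage for temporal and quadrate adductor muscle groups,
    two-dimensional plane-strain finite element models of an anterior bite
    with constant-stress force scaling, mesh-weighted arithmetic mean
    (MWAM) strain and the intervals method, and phylogenetic comparative
    statistics (Blomberg's K, multivariate K, PGLS under Brownian motion).
    A synthetic-skull study generator with controlled deformation modes,
    meshed fenestrate skull domains, lever points and traits evolved by
    Brownian motion on a phylogeny provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    deldir,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    utils,
    withr
Suggests:
    knitr,
    MASS,
    nlme,
    phytools,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
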