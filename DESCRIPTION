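Package: parchr
Title: Residue-Level Hydropathy Profiling of Proteins and Their
    Post-Translational Modifications by Simulated Water Evaporation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the PARCH (Protocol for Assigning a Residue's
    Character on a Hydropathy scale) analysis stack for proteins carrying
    post-translational modifications. Builds the thin explicit water-shell
    annealing system (shell carving, counter-ion placement, restraint and
    annealing-parameter templates for an external molecular dynamics
    engine), converts annealing trajectories into per-residue water-contact
    evaporation profiles and 0-10 PARCH hydropathy values with replicate
    aggregation, and quantifies modification-induced hydropathy change at
    phosphorylation, acetylation and methylation sites and their 3 Angstrom
    neighborhoods, including significance classification against a +/-0.2
    threshold and paired exact Wilcoxon signed-rank testing. A synthetic
    trajectory generator with analytic ground truth makes the whole stack
    testable without a molecular dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
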