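Package: ovoidtim
Title: Blueprint Arithmetic, Parametric Backbones and Validation Metrics for Ovoid TIM Barrels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and validating eight-stranded (beta/alpha)
    TIM-barrel proteins with elongated ("ovoid") barrel cross-sections.
    Implements barrel blueprint arithmetic (strand lengths, register shifts,
    shear number, twofold repeats, core layers and C-beta strips), parametric
    generation of idealized circular and ovoid barrel backbones, quantitative
    barrel-geometry analysis (strand assignment from hydrogen-bond ladders,
    axis and ellipse fitting, eccentricity, shear measurement, Kabsch
    superposition and repeat-symmetry RMSD), ILV hydrophobic-cluster contact
    statistics with solvent-accessible-surface buried areas, two-state
    chemical-denaturation curve simulation and fitting (linear extrapolation
    model), and an iterative-enrichment fixed-backbone sequence design loop
    with a pluggable energy function. Includes deterministic synthetic-data
    generators (preset barrels, decoys, mutation variants, denaturation-curve
    panels) so the full pipeline is testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
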