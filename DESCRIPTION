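Package: kaeff
Title: Effective Equilibrium Constants for Protein Assembly on Membranes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Equilibrium theory and simulators quantifying how reversible
    membrane localization of two soluble binding partners enhances their
    complex formation. Implements the effective equilibrium constant
    K_a^eff and its enhancement over the solution constant, the
    interpolated free-lipid solution, conversions between intrinsic and
    macroscopic association rates in 3D and 2D, deterministic mass-action
    reaction networks for protein-protein-lipid and scaffold-bridged
    systems with detailed balance, and a rule-based Gillespie simulator
    for higher-order assembly (clathrin lattice nucleation, BAR-domain
    oligomers). Ships parameter tables for clathrin-mediated endocytosis
    proteins and drivers that regenerate the principal computational
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
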