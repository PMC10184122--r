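Package: glueforce
Title: Hydrogen-Bond Robustness Analysis for Molecular-Glue Ternary Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the robustness of protein-protein hydrogen bonds
    stabilised by molecular glues such as lenalidomide. Provides a one-dimensional
    overdamped Langevin engine over a model hydrogen-bond rupture landscape with
    stochastic water-catalysis and a tunable hydrophobic-shielding parameter,
    steered-pulling work ensembles with stiff-spring guides, Jarzynski-equality
    potential-of-mean-force estimation with trajectory-level bootstrap errors and
    convergence diagnostics, water radial-distribution-function analysis of
    solvent shielding, aggregation of per-bond rupture free energies into
    per-complex totals with propagated errors, and one-site saturation-binding
    fits converting dissociation constants into binding free energies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
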