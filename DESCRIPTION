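Package: actioncsa
Title: Multiple Reaction Pathways by Global Optimization of the Onsager-Machlup Action
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global search for multiple, diverse transition pathways connecting two
    fixed endpoint configurations on analytic potential-energy surfaces. Pathways are
    represented as chains of states and scored by a gradient-only discretization of the
    Onsager-Machlup stochastic action; the search is a conformational space annealing
    (CSA) genetic algorithm that maintains a fixed-size bank of locally optimized
    pathways kept diverse by a discrete Frechet-distance cutoff annealed over the run.
    Local refinement minimizes the discretized classical action with a total-energy
    restraint, which requires only first derivatives of the potential. Includes an
    overdamped Langevin (Brownian dynamics) simulator with transition detection for
    validating pathway rank order against direct simulation, and an exhaustive
    enumerator of torsional transition pathways with symmetry reduction for assessing
    sampling completeness on rotamer-chain systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
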