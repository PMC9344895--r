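Package: treegibbs
Title: Gibbs Sampling of RNA Secondary-Structure Branching via Plane Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov chain Monte Carlo sampling of RNA secondary-structure
    branching configurations under the Nearest Neighbor Thermodynamic Model
    (NNTM). Secondary-structure branching is abstracted as a plane tree whose
    Gibbs weight depends only on the number of hairpins (leaves) and interior
    loops (internal nodes); trees are sampled through a four-move Markov
    chain on the bijective 2-Motzkin path representation. Includes the
    reduction of NNTM multiloop, helix and loop parameters to the tree energy
    coefficients, the plane-tree/2-Motzkin-path bijection and its inverse,
    exact enumeration oracles for small sizes (Gibbs distribution, full
    transition matrix, detailed-balance and spectral diagnostics), branching
    statistic dispersion summaries, and a command-line interface for
    reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
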