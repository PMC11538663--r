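Package: caclandscape
Title: Quasi-Potential Landscapes and Transition Paths for the
    Cancer-Adipose Conversion Gene Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the cancer-adipose conversion (CAC) circuit as a
    Hill-regulation gene-network ODE with drug input nodes (TGF-beta, MEK
    inhibitor, rosiglitazone), finds its attractors and one-parameter
    bifurcation diagrams, constructs quasi-potential landscapes U = -ln Pss
    via a self-consistent mean-field Gaussian approximation, computes
    Freidlin-Wentzell minimum action transition paths between cell-state
    attractors, and optimizes drug-target combinations by minimizing a
    transition-action objective (landscape control).  A Langevin simulator
    provides an independent stochastic oracle, and a synthetic-data module
    generates cluster-structured expression matrices for model-data
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    lhs,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
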