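Package: flexderiv
Title: Exact Derivatives of Observables under Flexible Holonomic Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes exact, parameter-free derivatives of position-dependent
    observables along a flexibly constrained subspace, where constrained
    internal coordinates are defined by potential-energy minimization at fixed
    unconstrained coordinates. Implements Z-matrix (SASMIC-style) internal
    coordinate kinematics in a body-fixed frame, analytic geometric derivatives
    of atomic positions via translation and Rodrigues-rotation generators, the
    Hessian sub-block linear solve for the constraint Jacobian, and a
    finite-difference comparator with re-minimization, step-size sweeps,
    normalized error metrics and precision-truncation experiments. Ships
    self-contained molecular fixtures (methanol-, N-methyl-acetamide- and
    tri-glycine-like topologies), a synthetic internal-coordinate force field
    with controllable stiffness and couplings, and a closed-form 2D toy system.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
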