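Package: mlscf
Title: Unrestricted Multilevel Hartree-Fock and DFT with Classical Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Open-shell multilevel electronic-structure calculations for
    molecules in complex environments. The alpha and beta one-particle density
    matrices are split into an active block, optimized self-consistently, and
    an inactive block kept frozen after a partial pivoted Cholesky
    decomposition restricted to atomic orbitals of user-selected active atoms;
    virtual spaces are spanned by projected atomic orbitals. The quantum region
    can be embedded in a nonpolarizable point-charge layer or a polarizable
    fluctuating-charge layer with per-fragment charge constraints. Includes a
    Gaussian-integral engine (McMurchie-Davidson), LSDA/PBE/PBE0 exchange-
    correlation with Becke quadrature, Fermi-contact hyperfine coupling
    constants for radicals, and a solvation-snapshot pipeline with a synthetic
    droplet generator and ensemble statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
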