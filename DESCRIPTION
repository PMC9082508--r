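Package: statescape
Title: Geometric Energy Landscapes for State-Specific Electronic Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring the exact electronic energy as a landscape
    constrained to the unit hypersphere of normalized configuration-interaction
    coefficient vectors. Provides tangent-space gradients and constrained
    Hessians for arbitrary real symmetric Hamiltonians, enumeration and
    saddle-index classification of the exact stationary points, gradient
    extremals (geodesics) between eigenstates, the identity linking the
    squared energy gradient to the Hamiltonian variance, and folded-spectrum
    objectives. Includes a self-contained minimal-basis (STO-3G) model of
    singlet H2 built from closed-form s-type Gaussian integrals, together
    with the one-parameter restricted Hartree-Fock and two-parameter
    excited-state mean-field submanifolds of its three-state hypersphere,
    and searches for constrained stationary points of the energy, the
    variance (sigma-SCF analogue), and the local square-gradient (SGM
    analogue) on those submanifolds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
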