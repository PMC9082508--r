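# statescape

Geometric energy landscapes for state-specific electronic structure.

## The problem

In a finite Hilbert space the exact electronic wave function is a linear
combination of many-particle basis states, |Ψ⟩ = Σ_I c_I |Φ_I⟩, and
normalization confines the coefficient vector **c** to the unit hypersphere
‖**c**‖ = 1. The energy is the quadratic form E(**c**) = **c**ᵀ**H c**, and
every exact eigenstate appears as a *pair* of stationary points ±**c**_k of
this landscape. The constrained (tangent-space) derivatives are

- gradient: ∇E = **c**⊥ᵀ (2**H c**), which vanishes iff **Hc** = E**c**;
- Hessian: Q̃ = 2 **c**⊥ᵀ (**H** − E(**c**) **I**) **c**⊥, whose eigenvalues
  at the k-th eigenstate are twice the excitation energies 2(E_i − E_k).

Consequences this package computes and tests:

- the k-th excited state is an index-k saddle (k downhill directions); the
  landscape has exactly two minima (±ground state) and no other local minima;
- the whole spectrum is encoded at any single stationary point (energy plus
  half the Hessian eigenvalues);
- |∇E|² = 4 (⟨H²⟩ − ⟨H⟩²) — the squared gradient norm *is* four times the
  Hamiltonian variance, which fixes the global structure of variance-
  minimization landscapes: eigenstates are variance zeros separated by
  barriers of height ΔE² at the midpoints of the geodesics connecting them.

Approximate ansätze (restricted Hartree–Fock; excited-state mean-field,
ESMF) are *submanifolds* of the hypersphere, and their SCF solutions are
stationary points of the energy (or of the variance, for σ-SCF-type
methods) constrained to those submanifolds. The package ships a fully
self-contained minimal-basis (STO-3G) model of singlet H₂ — integrals are
evaluated internally from closed-form s-type Gaussian formulas — whose
three-state hypersphere makes every one of these statements concretely
computable: a one-angle RHF circle c(ϕ) = (cos²ϕ, √2 cosϕ sinϕ, sin²ϕ) and
a two-angle ESMF surface c(θ, ϕ) = cosθ·c_ref(ϕ) + sinθ·c_os(ϕ).

Intended users: method developers studying state-specific and
variance-based excited-state solvers, and anyone wanting a transparent,
dependency-light playground for Riemannian views of electronic structure.

## Worked example

```r
library(statescape)

H <- build_csf_hamiltonian(1.437707)   # equilibrium bond length, bohr
H
#> Singlet CSF Hamiltonian, H2/STO-3G, R = 1.437707 bohr
#>                    sigma_g^2 open-shell singlet sigma_u^2
#> sigma_g^2          -1.115312           0.000000  0.182381
#> open-shell singlet  0.000000          -0.190547  0.000000
#> sigma_u^2           0.182381           0.000000  0.413860
#> eigenvalues (hartree):  0.435311 -0.190547 -1.136763
```

The diagonal entries are the total energies (nuclear repulsion included) of
the σ_g², open-shell singlet and σ_u² configurations; the only off-diagonal
coupling is the exchange integral (σ_gσ_u|σ_gσ_u) between the two closed
shells, and the eigenvalues are the three exact singlet states.

```r
enumerate_stationary_points(build_csf_hamiltonian(2)$matrix)
#> Exact stationary points on the unit hypersphere (6 points)
#>   state_index sign      energy hessian_index          label degenerate
#> 1           0    1 -1.08849613             0        minimum      FALSE
#> 2           0   -1 -1.08849613             0        minimum      FALSE
#> 3           1    1 -0.37392225             1 index-1 saddle      FALSE
#> 4           1   -1 -0.37392225             1 index-1 saddle      FALSE
#> 5           2    1 -0.02669576             2        maximum      FALSE
#> 6           2   -1 -0.02669576             2        maximum      FALSE
```

Each eigenstate appears as a sign pair and the Hessian index climbs with
the excitation level. Scanning the two-parameter ESMF surface at the
equilibrium geometry:

```r
find_stationary_points(esmf_embedding(), H$matrix, "energy")
#> Constrained stationary points (esmf ansatz, energy objective): 4 solution(s)
#>           theta      phi     energy      value hessian_index          label
#> 1 -5.025836e-01 0.330385 -1.1367634 -1.1367634             0        minimum
#> 2  0.000000e+00 0.000000 -1.1153120 -1.1153120             1 index-1 saddle
#> 3  1.570796e+00 0.000000 -0.1905466 -0.1905466             1 index-1 saddle
#> 4  8.881784e-16 1.570796  0.4138596  0.4138596             2        maximum
```

The RHF ground state (θ = ϕ = 0, energy −1.115312) is *not* the ESMF
minimum: it turns into an index-1 saddle, and the true minimum at
(θ, ϕ) = (−0.5026, 0.3304) recovers the exact ground-state energy
−1.136763 hartree — simultaneous orbital and CI relaxation lowers the
energy below the best single determinant. The open-shell singlet
(θ = π/2, ϕ = 0) is reached exactly as an index-1 saddle, while the doubly
excited state stays the closed-shell σ_u² maximum.

A thin command-line front end over the same functions is installed at
`inst/cli/statescape.R`:

```sh
Rscript inst/cli/statescape.R h2 hamiltonian --bond-length 2 --out h2.json
Rscript inst/cli/statescape.R landscape stationary --hamiltonian h2.json
Rscript inst/cli/statescape.R ansatz scan --ansatz rhf --bond-length 3 --objective variance
```

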