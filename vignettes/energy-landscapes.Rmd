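---
title: "Energy landscapes of exact and approximate electronic states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy landscapes of exact and approximate electronic states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statescape)
```

## The model

For an $N$-dimensional Hilbert space spanned by orthonormal many-particle
basis states, a normalized real wave function is a unit vector
$\mathbf{c} \in \mathbb{R}^N$ and its energy is the quadratic form
$E(\mathbf{c}) = \mathbf{c}^{\mathsf T}\mathbf{H}\,\mathbf{c}$ on the unit
hypersphere $S^{N-1}$. The package works with three layers of this picture:

1. **Exact landscape** (`state_energy()`, `local_gradient()`,
   `local_hessian()`, `enumerate_stationary_points()`). The tangent space at
   $\mathbf{c}$ is spanned by the columns of an $N\times(N-1)$ matrix
   $\mathbf{c}_\perp$ with $\mathbf{c}_\perp^{\mathsf T}\mathbf{c} = 0$ and
   $\mathbf{c}\mathbf{c}^{\mathsf T} +
   \mathbf{c}_\perp\mathbf{c}_\perp^{\mathsf T} = \mathbf{I}$. The
   constrained gradient is $\nabla E =
   \mathbf{c}_\perp^{\mathsf T}(2\mathbf{H}\mathbf{c})$ and the constrained
   Hessian is $\tilde{\mathbf{Q}} = 2\,\mathbf{c}_\perp^{\mathsf T}
   (\mathbf{H} - E(\mathbf{c})\mathbf{I})\mathbf{c}_\perp$. Stationary
   points are exactly the eigenvector sign pairs $\pm\mathbf{c}_k$; at the
   $k$-th one the Hessian eigenvalues are $2(E_i - E_k)$, so its index
   equals the excitation level and the full spectrum is recoverable from
   any single stationary point (`spectrum_from_stationary_point()`).

2. **Geodesics and the variance** (`geodesic_path()`,
   `hamiltonian_variance()`, `barrier_catalog()`, `folded_spectrum()`).
   Between two eigenstates the gradient extremal is the great-circle arc
   $\cos\theta\,\mathbf{c}_i + \sin\theta\,\mathbf{c}_j$, along which
   $E(\theta) = E_i\cos^2\theta + E_j\sin^2\theta$ and $|\nabla E|^2 =
   \Delta E_{ji}^2 \sin^2 2\theta$. Everywhere on the sphere
   $|\nabla E|^2 = 4(\langle H^2\rangle - \langle H\rangle^2)$, so the
   variance landscape consists of eigenstate zeros separated by barriers of
   height $\Delta E^2$ at the midpoints $\theta = \pi/4$, the lowest barrier
   always joining states adjacent in energy.

3. **Ansatz submanifolds** (`rhf_embedding()`, `esmf_embedding()`,
   `find_stationary_points()`). For minimal-basis H$_2$ the three singlet
   configuration state functions (CSFs) $\{\sigma_g^2,\ (|\sigma_g\bar\sigma_u\rangle +
   |\sigma_u\bar\sigma_g\rangle)/\sqrt2,\ \sigma_u^2\}$ span the exact
   space, the closed-shell RHF determinants trace the one-angle circle
   $c(\phi) = (\cos^2\phi,\ \sqrt2\cos\phi\sin\phi,\ \sin^2\phi)$, and the
   ESMF ansatz adds a CI angle mixing in the open-shell singlet of the
   rotated orbital pair,
   $c(\theta,\phi) = \cos\theta\,c_{\mathrm{ref}}(\phi) +
   \sin\theta\,c_{\mathrm{os}}(\phi)$ with
   $c_{\mathrm{os}}(\phi) = (-\sin 2\phi/\sqrt2,\ \cos 2\phi,\
   \sin 2\phi/\sqrt2)$. Because the trigonometric maps keep the
   normalization exact, plain parameter derivatives of the composed
   objective are the constrained derivatives; first and second derivatives
   of both maps are implemented analytically.

The assumptions inherited from this construction: real-valued wave
functions and Hamiltonians, an orthonormal many-particle basis, and (for
the built-in model) two electrons in two symmetry-adapted orbitals. Atomic
units (hartree, bohr) are used throughout with no conversions inside the
core.

## The built-in H$_2$ model

`build_csf_hamiltonian(R)` assembles the $3\times 3$ singlet Hamiltonian at
bond length $R$ (bohr) from scratch: the canonical STO-3G three-Gaussian
1s contraction with the standard hydrogen scale factor $\zeta = 1.24$
(exponents scale as $\zeta^2$), closed-form s-type Gaussian integrals via
the Gaussian product theorem and the Boys function
$F_0(x) = \int_0^1 e^{-xt^2}dt$, symmetry-adapted molecular orbitals
$\sigma_{g/u} = (\chi_1 \pm \chi_2)/\sqrt{2(1\pm S_{12})}$, and the
Slater–Condon rules for the two-electron singlet CSFs.

Two conventions are fixed here once and used consistently downstream:

* **Nuclear repulsion is included** on the diagonal ($+1/R$), so landscape
  energies are total energies and stationary-point energies can be compared
  directly across geometries. A constant shift changes no gradient, Hessian
  or barrier height.
* **Phases**: $\sigma_g$ has equal-sign AO coefficients and $\sigma_u$ has
  a positive first coefficient; the open-shell singlet CSF is
  $(|\sigma_g\bar\sigma_u\rangle + |\sigma_u\bar\sigma_g\rangle)/\sqrt2$.
  All $(\theta,\phi)$ coordinates depend on these phases; with them, the
  ESMF global minimum at the equilibrium geometry falls at
  $(\theta, \phi) = (\mp 0.5026, \pm 0.3304)$ — the two angles always
  rotate in opposite senses, and the mirror pair maps to the same state
  because the ground state has no open-shell (ungerade) component.

A physical point worth recording: in this minimal basis the open-shell
singlet expands to the ionic combination $\chi_1^2 - \chi_2^2$, so at
dissociation the *two upper* singlets (ungerade and gerade ionic states)
become degenerate while the covalent ground state stays roughly
0.75 hartree below them. There is no closing covalent/open-shell gap; the
test suite asserts the correct limit.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `R` | `build_csf_hamiltonian()` | — | bond length, bohr; model valid over $[0.8, 10]$ for curve tracking |
| `zeta` | `sto3g_hydrogen()` | 1.24 | Slater exponent of the hydrogen 1s shell (standard molecular value) |
| `grid_density` | `find_stationary_points()` | 720 | grid points per parameter for the periodic scan; 720 resolves every feature of these one- and two-angle landscapes with a large margin (solution counts are stable from well below 64) |
| `stationary_tol` | searches | 1e-9 | accepted gradient norm (hartree-scale problems in double precision) |
| `index_tol` | classification | 1e-9 | Hessian eigenvalues within this of zero are not counted negative |
| `dedup_tol` | searches | 1e-6 | embedded 3-vectors equal up to overall sign within this are one solution |
| `degeneracy_tol` | `enumerate_stationary_points()` | 1e-8 | Hessian eigenvalue gap below which a stationary point is flagged as part of a degenerate continuum |

## Numerical choices

* **Boys function**: Taylor series below $x = 0.03$ (nine terms, truncation
  $<10^{-19}$), otherwise $\tfrac12\sqrt{\pi/x}\,\mathrm{erf}\sqrt{x}$ with
  erf evaluated through the normal CDF; relative accuracy better than
  $10^{-12}$ across the switch point.
* **Tangent frames** are built by a deterministic Householder reflector
  mapping $\mathbf{c}$ to the first coordinate axis. Any orthogonal mixing
  of the frame columns is an equally valid gauge; only frame-invariant
  quantities (gradient norm, Hessian spectrum and index) are physically
  meaningful, and the API documents raw frame coordinates as
  gauge-dependent.
* **Stationary-point search** is grid-then-polish rather than multi-start
  quasi-Newton: on 1- and 2-parameter periodic landscapes an exhaustive
  scan is cheap and cannot miss solutions. Candidates are local minima of
  the squared parameter-gradient norm over the full (wrapped) grid
  neighbourhood — detection by sign change alone would miss roots pinned
  exactly on symmetry nodes such as $\phi = 0$. Each candidate is polished
  by damped Newton iteration on the analytic gradient (steps capped at 0.2
  rad, singular-Hessian fallback to a gradient step); non-convergent
  candidates are dropped with a warning, never merged. De-duplication
  compares embedded 3-vectors up to overall sign ($10^{-6}$), which is
  immune to parameter aliasing; the reported representative is reduced to
  $\theta \in (-\pi/2, \pi/2]$ (using the sign copy
  $\theta \to \theta - \pi$) and $\phi \in (-\pi/2, \pi/2]$.
* **Derivatives**: energy and variance use exact ambient
  gradients/Hessians composed with the analytic map derivatives (for the
  variance, $\nabla f = 2\mathbf{H}^2\mathbf{c} - 4E\,\mathbf{H}\mathbf{c}$
  and $\nabla^2 f = 2\mathbf{H}^2 - 4E\mathbf{H} -
  8(\mathbf{H}\mathbf{c})(\mathbf{H}\mathbf{c})^{\mathsf T}$). The
  square-gradient objective has an analytic gradient through the embedding
  second derivatives; its parameter Hessian would need third derivatives of
  the map and uses central differences of the analytic gradient
  (step $10^{-5}$) instead.
* **Degenerate eigenvalues** of the input Hamiltonian are reported with an
  arbitrary orthonormal basis of the degenerate subspace and a continuum
  flag: any linear combination of degenerate eigenvectors is stationary,
  so no canonical choice exists.
* **Degeneracy grouping** of constrained solutions keys on objective value
  *and* energy jointly: at $R = 3$ the $\sigma_g^2$ and $\sigma_u^2$
  configurations happen to share a variance value while being entirely
  different states.
* **Stereographic projection** uses $X = c_1/(1+c_2)$, $Y = c_3/(1+c_2)$,
  i.e. the chart centred on the open-shell singlet $(0,1,0)$ whose
  antipode maps to infinity; the pole returns `Inf` coordinates rather
  than an error. The orientation of the $X/Y$ axes is a convention.

## What the synthetic fixtures emulate

`random_hamiltonian(eigenvalues, seed)` draws a Haar-like random orthogonal
frame (sign-fixed QR of a Gaussian matrix) around a prescribed spectrum.
This is the right fixture for every *landscape* theorem in the package —
index ladders, the gradient/variance identity, spectrum reconstruction,
barrier ordering — because those results depend on nothing but real
symmetry of $\mathbf{H}$. What such fixtures do **not** emulate is the
structure of physical electronic Hamiltonians: sparsity, spin and point
group symmetry (and hence symmetry-pinned stationary points), or realistic
spectral densities. Passing the property tests therefore certifies the
differential geometry, not any chemistry; the chemistry is exercised
separately by the H$_2$ model, whose integrals are pinned against
independent quadrature oracles in the test suite.

Problem sizes in the tests — random matrices of dimension 3–10, roughly a
thousand draws for the variance identity, grids of 360–720 points per
angle — were chosen so that each property is sampled well past the point
where failures of an incorrect implementation become certain, while the
whole suite stays interactive-fast.

## Known limitations

* Real wave functions only; complex landscapes (where sign pairs become
  continuous phase circles) are out of scope.
* The ansatz layer implements the two-orbital closed-shell rotation and
  its ESMF extension; general many-orbital rotations, unrestricted
  determinants, and larger basis sets are not covered.
* General gradient-extremal path following is deliberately absent: on the
  exact landscape the extremals *are* the eigenstate geodesics, which are
  constructed analytically. `extremal_residual()` verifies the defining
  eigenvector condition pointwise instead.
* The iterative σ-SCF and SGM algorithms themselves are not implemented;
  the package characterizes their solution sets as constrained stationary
  points of the variance and of the local square-gradient, which is what
  fixes where those algorithms can converge.
* Dense diagonalization bounds practical Hilbert-space sizes to a few
  thousand states.
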