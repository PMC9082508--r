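#' Point on the geodesic between two orthogonal states
#'
#' On the exact landscape the gradient extremal connecting two eigenstates is
#' the great-circle arc \eqn{c(\theta) = \cos\theta\, c_i + \sin\theta\, c_j}.
#'
#' @param c_i,c_j Orthonormal endpoint vectors (typically eigenvectors).
#' @param theta Angle(s) in radians; `0` gives `c_i`, `pi/2` gives `c_j`.
#' @return Unit vector (or matrix with one column per `theta`).
#' @export
geodesic_point <- function(c_i, c_j, theta) {
  c_i <- as.numeric(c_i); c_j <- as.numeric(c_j)
  if (abs(sum(c_i * c_j)) > 1e-10) {
    stop("geodesic endpoints must be orthogonal", call. = FALSE)
  }
  if (length(theta) == 1L) {
    cos(theta) * c_i + sin(theta) * c_j
  } else {
    outer(c_i, cos(theta)) + outer(c_j, sin(theta))
  }
}

#' Energy along an eigenstate-pair geodesic
#'
#' Closed form \eqn{E(\theta) = E_i \cos^2\theta + E_j \sin^2\theta}.
#'
#' @param theta Angle(s) in radians.
#' @param E_i,E_j Endpoint eigenvalues (hartree).
#' @return Energy (hartree).
#' @export
energy_along <- function(theta, E_i, E_j) {
  E_i * cos(theta)^2 + E_j * sin(theta)^2
}

#' Squared gradient norm along an eigenstate-pair geodesic
#'
#' Closed form \eqn{|\nabla E|^2(\theta) = \Delta E_{ji}^2 \sin^2(2\theta)}:
#' zero at both eigenstates and maximal, with the barrier height
#' \eqn{\Delta E_{ji}^2}, at the inflection point \eqn{\theta = \pi/4}.
#'
#' @param theta Angle(s) in radians.
#' @param delta_E Energy gap \eqn{E_j - E_i} (hartree).
#' @return Squared gradient (hartree^2).
#' @export
square_gradient_along <- function(theta, delta_E) {
  delta_E^2 * sin(2 * theta)^2
}

#' Sampled geodesic between two eigenstates of a Hamiltonian
#'
#' Builds the gradient extremal connecting eigenstates `i` and `j` of `H`
#' (0-based excitation indices) and samples energy and squared gradient on a
#' uniform grid over the quarter circle \eqn{\theta \in [0, \pi/2]}.
#'
#' @param H Real symmetric matrix.
#' @param i,j 0-based eigenstate indices (ascending energy order).
#' @param n Number of grid points.
#' @return Object of class `geodesic_path`: list with `endpoint_indices`,
#'   `theta`, `points` (N x n matrix), `energies`, `square_gradients`.
#' @export
geodesic_path <- function(H, i, j, n = 101) {
  check_symmetric(H)
  N <- nrow(H)
  if (i == j || i < 0 || j < 0 || i >= N || j >= N) {
    stop("`i` and `j` must be distinct 0-based eigenstate indices", call. = FALSE)
  }
  eig <- eigen(H, symmetric = TRUE)
  evals <- rev(eig$values)
  evecs <- eig$vectors[, N:1, drop = FALSE]
  th <- seq(0, pi / 2, length.out = n)
  pts <- geodesic_point(evecs[, i + 1], evecs[, j + 1], th)
  structure(
    list(endpoint_indices = c(i, j),
         theta = th,
         points = pts,
         energies = energy_along(th, evals[i + 1], evals[j + 1]),
         square_gradients = square_gradient_along(th, evals[j + 1] - evals[i + 1])),
    class = "geodesic_path"
  )
}

#' Gradient-extremal residual
#'
#' A point lies on a gradient extremal when the local gradient is an
#' eigenvector of the constrained local Hessian. The residual is the norm of
#' the component of \eqn{\tilde Q \nabla E} orthogonal to \eqn{\nabla E};
#' it vanishes on extremals and, by convention, at stationary points
#' (where the gradient itself vanishes).
#'
#' @inheritParams state_energy
#' @param stationary_tol Gradient norms below this return an exact 0.
#' @return Non-negative residual norm.
#' @export
extremal_residual <- function(c, H, stationary_tol = 1e-9, norm_tol = 1e-8) {
  fr <- tangent_frame(c)
  g <- local_gradient(fr$point, H, fr, norm_tol)
  gn2 <- sum(g^2)
  if (sqrt(gn2) < stationary_tol) return(0)
  Q <- local_hessian(fr$point, H, fr, norm_tol)
  Qg <- drop(Q %*% g)
  r <- Qg - (sum(g * Qg) / gn2) * g
  sqrt(sum(r^2))
}

#' Hamiltonian variance
#'
#' \eqn{\sigma^2(c) = \langle H^2\rangle - \langle H\rangle^2
#'   = c^T H^2 c - (c^T H c)^2}. Zero exactly at eigenstates, and equal to
#' one quarter of the squared local gradient norm everywhere on the
#' hypersphere.
#'
#' @inheritParams state_energy
#' @return Variance (hartree^2), non-negative.
#' @export
hamiltonian_variance <- function(c, H, norm_tol = 1e-8) {
  check_state(c, H, norm_tol)
  Hc <- drop(H %*% c)
  max(0, sum(Hc^2) - sum(c * Hc)^2)
}

#' Folded-spectrum objective
#'
#' \eqn{\langle (H - \omega)^2 \rangle = \sigma^2(c) + (E(c) - \omega)^2},
#' minimized over exact eigenstates by the one with energy closest to the
#' target \eqn{\omega}.
#'
#' @inheritParams state_energy
#' @param omega Target energy (hartree).
#' @return Objective value (hartree^2).
#' @export
folded_spectrum <- function(c, H, omega, norm_tol = 1e-8) {
  E <- state_energy(c, H, norm_tol)
  hamiltonian_variance(c, H, norm_tol) + (E - omega)^2
}

#' Catalog of variance barriers between eigenstates
#'
#' Each unordered pair of eigenstates is connected by a gradient extremal
#' carrying a square-gradient barrier of height \eqn{\Delta E^2} at the
#' inflection point \eqn{\theta = \pi/4}. The lowest barrier always joins
#' states adjacent in energy.
#'
#' @param H Real symmetric matrix.
#' @return A `data.frame` with one row per pair, sorted by ascending barrier
#'   height: columns `i`, `j` (0-based state indices), `height` (hartree^2),
#'   `inflection_theta` (radians, always `pi/4`), `adjacency_rank`
#'   (`|i - j|`).
#' @export
barrier_catalog <- function(H) {
  check_symmetric(H)
  evals <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  n <- length(evals)
  pairs <- utils::combn(n, 2)
  out <- data.frame(
    i = pairs[1, ] - 1L,
    j = pairs[2, ] - 1L,
    height = (evals[pairs[2, ]] - evals[pairs[1, ]])^2,
    inflection_theta = pi / 4,
    adjacency_rank = pairs[2, ] - pairs[1, ]
  )
  out[order(out$height), , drop = FALSE]
}
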