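#' Energy of a normalized state vector
#'
#' The electronic energy of a wave function represented by a unit coefficient
#' vector `c` in an orthonormal many-particle basis is the quadratic form
#' \eqn{E(c) = c^T H c}.
#'
#' @param c Numeric coefficient vector of unit Euclidean norm.
#' @param H Real symmetric Hamiltonian matrix (hartree).
#' @param norm_tol Allowed deviation of `|c|` from 1.
#' @return Energy in hartree.
#' @export
state_energy <- function(c, H, norm_tol = 1e-8) {
  check_state(c, H, norm_tol)
  drop(crossprod(c, H %*% c))
}

#' Global energy gradient in the full Hilbert space
#'
#' The unconstrained gradient of \eqn{c^T H c} is \eqn{2Hc}. At an exact
#' eigenstate it is (anti)parallel to `c` and therefore has no tangential
#' component on the unit hypersphere.
#'
#' @inheritParams state_energy
#' @return Numeric vector `2 H c`.
#' @export
global_gradient <- function(c, H, norm_tol = 1e-8) {
  check_state(c, H, norm_tol)
  drop(2 * (H %*% c))
}

#' Orthonormal tangent frame at a point on the unit hypersphere
#'
#' Deterministically completes the unit vector `c` to an orthonormal basis of
#' its tangent space using a Householder reflector that maps `c` onto the
#' first coordinate axis; the remaining columns of the (symmetric,
#' orthogonal) reflector span the tangent space. The frame satisfies
#' \eqn{c_\perp^T c = 0} and the completeness relation
#' \eqn{c c^T + c_\perp c_\perp^T = I}.
#'
#' Individual frame vectors are gauge-dependent (any orthogonal mixing of the
#' columns is an equally valid frame); only frame-invariant quantities such
#' as gradient norms and Hessian spectra carry physical meaning.
#'
#' @param c Unit-norm numeric vector of length N >= 2.
#' @return An object of class `tangent_frame`: list with `point` (the input
#'   vector, renormalized) and `basis` (N x (N-1) matrix of orthonormal
#'   tangent vectors).
#' @export
tangent_frame <- function(c) {
  c <- as.numeric(c)
  n <- length(c)
  nrm <- sqrt(sum(c^2))
  if (n < 2 || nrm < 1e-12) {
    stop("`c` must be a nonzero vector of length >= 2", call. = FALSE)
  }
  c <- c / nrm
  s <- if (c[1] >= 0) 1 else -1
  u <- c
  u[1] <- u[1] + s
  # Householder reflector I - 2 u u^T / (u^T u); column 1 is -s*c,
  # columns 2..N are orthonormal and orthogonal to c
  Hh <- diag(n) - 2 * tcrossprod(u) / sum(u^2)
  structure(list(point = c, basis = Hh[, -1, drop = FALSE]),
            class = "tangent_frame")
}

#' Local (tangent-space) energy gradient
#'
#' Projects the global gradient into the tangent space of the hypersphere:
#' \eqn{\nabla E = c_\perp^T (2 H c)}. It vanishes exactly when `c` is an
#' eigenvector of `H`, and its squared norm equals four times the
#' Hamiltonian variance at `c`.
#'
#' @inheritParams state_energy
#' @param frame A [tangent_frame()] built at `c` (built on the fly when
#'   omitted).
#' @return Numeric vector of length N-1 (frame coordinates; gauge-dependent,
#'   but its norm is not).
#' @export
local_gradient <- function(c, H, frame = tangent_frame(c), norm_tol = 1e-8) {
  check_state(c, H, norm_tol)
  check_frame(frame, c)
  drop(crossprod(frame$basis, 2 * (H %*% c)))
}

#' Constrained local Hessian on the hypersphere
#'
#' The second derivative of the energy along the sphere, obtained by shifting
#' the Hamiltonian by the current energy and projecting into the tangent
#' space: \eqn{\tilde Q = 2\, c_\perp^T (H - E(c) I)\, c_\perp}. At the k-th
#' eigenstate its eigenvalues are twice the excitation energies
#' \eqn{2(E_i - E_k)}, so the number of negative eigenvalues equals the
#' excitation level.
#'
#' @inheritParams local_gradient
#' @return Symmetric (N-1) x (N-1) matrix (hartree).
#' @export
local_hessian <- function(c, H, frame = tangent_frame(c), norm_tol = 1e-8) {
  check_state(c, H, norm_tol)
  check_frame(frame, c)
  E <- drop(crossprod(c, H %*% c))
  B <- frame$basis
  Q <- 2 * crossprod(B, (H %*% B) - E * B)
  (Q + t(Q)) / 2
}

#' Energy, gradient and Hessian at a point
#'
#' Convenience bundle of [state_energy()], [local_gradient()] and
#' [local_hessian()] sharing one [tangent_frame()].
#'
#' @inheritParams state_energy
#' @return Object of class `local_curvature`: list with `energy`,
#'   `local_gradient`, `local_hessian`, `frame`.
#' @export
local_curvature <- function(c, H, norm_tol = 1e-8) {
  fr <- tangent_frame(c)
  structure(
    list(energy = state_energy(fr$point, H, norm_tol),
         local_gradient = local_gradient(fr$point, H, fr, norm_tol),
         local_hessian = local_hessian(fr$point, H, fr, norm_tol),
         frame = fr),
    class = "local_curvature"
  )
}

#' Enumerate and classify the exact stationary points
#'
#' On the exact landscape the stationary points of the energy constrained to
#' the unit hypersphere are precisely the eigenvectors of `H`; each
#' eigenstate appears twice, as a sign-related pair `+c_k`, `-c_k`. Every
#' pair is classified by the spectrum of the constrained local Hessian: the
#' ground state gives the only two minima, the k-th excited state an
#' index-k saddle pair, and the highest state the two maxima. Stationary
#' points whose Hessian has a zero eigenvalue (degenerate eigenvalues of
#' `H`) are flagged as members of a flat continuum.
#'
#' @param H Real symmetric matrix.
#' @param degeneracy_tol Hessian eigenvalues with absolute value below this
#'   are treated as zero when flagging degenerate continua.
#' @return Object of class `stationary_points`: a list of `2N` records
#'   sorted by energy, each with fields `point`, `energy`, `hessian_index`,
#'   `hessian_eigenvalues`, `label`, `state_index` (0-based excitation
#'   level), `sign` (+1/-1) and `degenerate`. Use `as.data.frame()` for a
#'   tabular view.
#' @examples
#' H <- build_csf_hamiltonian(2)$matrix
#' as.data.frame(enumerate_stationary_points(H))
#' @export
enumerate_stationary_points <- function(H, degeneracy_tol = 1e-8) {
  check_symmetric(H)
  eig <- eigen(H, symmetric = TRUE)
  n <- nrow(H)
  evals <- rev(eig$values)           # ascending
  evecs <- eig$vectors[, n:1, drop = FALSE]
  pts <- list()
  for (k in seq_len(n)) {
    hess_ev <- sort(2 * (evals[-k] - evals[k]))
    idx <- sum(hess_ev < -degeneracy_tol)
    degenerate <- any(abs(hess_ev) < degeneracy_tol)
    label <- if (idx == 0 && max(hess_ev) > degeneracy_tol) "minimum"
      else if (idx == n - 1) "maximum"
      else if (degenerate && idx == 0 && max(abs(hess_ev)) < degeneracy_tol)
        "degenerate continuum"
      else paste0("index-", idx, " saddle")
    for (s in c(1, -1)) {
      pts[[length(pts) + 1L]] <- list(
        point = s * evecs[, k],
        energy = evals[k],
        hessian_index = idx,
        hessian_eigenvalues = hess_ev,
        label = label,
        state_index = k - 1L,
        sign = s,
        degenerate = degenerate
      )
    }
  }
  structure(pts, class = "stationary_points")
}

#' @export
as.data.frame.stationary_points <- function(x, ...) {
  data.frame(
    state_index = vapply(x, `[[`, 0L, "state_index"),
    sign = vapply(x, `[[`, 0, "sign"),
    energy = vapply(x, `[[`, 0, "energy"),
    hessian_index = vapply(x, `[[`, 0L, "hessian_index"),
    label = vapply(x, `[[`, "", "label"),
    degenerate = vapply(x, `[[`, TRUE, "degenerate")
  )
}

#' @export
print.stationary_points <- function(x, ...) {
  cat("Exact stationary points on the unit hypersphere (", length(x),
      " points)\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' Reconstruct the full spectrum from one stationary point
#'
#' At an exact stationary point the complete eigenvalue spectrum of `H` is
#' encoded locally: it is the point's own energy together with
#' \eqn{E_k + \lambda_i/2} for every constrained-Hessian eigenvalue
#' \eqn{\lambda_i}.
#'
#' @param c Unit vector at a stationary point (an eigenvector of `H`), or a
#'   record from [enumerate_stationary_points()].
#' @param H Real symmetric matrix (ignored if `c` carries its own energy and
#'   Hessian spectrum and `H` is missing).
#' @param stationary_tol Maximum allowed local-gradient norm.
#' @return Sorted numeric vector of all N eigenvalues (hartree).
#' @export
spectrum_from_stationary_point <- function(c, H, stationary_tol = 1e-9) {
  if (is.list(c) && !is.null(c$hessian_eigenvalues)) {
    return(sort(c(c$energy, c$energy + c$hessian_eigenvalues / 2)))
  }
  fr <- tangent_frame(c)
  g <- local_gradient(fr$point, H, fr)
  if (sqrt(sum(g^2)) > stationary_tol) {
    stop("point is not stationary: local gradient norm ",
         format(sqrt(sum(g^2))), " exceeds tolerance", call. = FALSE)
  }
  E <- state_energy(fr$point, H)
  lam <- eigen(local_hessian(fr$point, H, fr), symmetric = TRUE,
               only.values = TRUE)$values
  sort(c(E, E + lam / 2))
}

#' Stereographic projection of a three-state hypersphere
#'
#' Maps a unit 3-vector `(c1, c2, c3)` to plane coordinates
#' \eqn{X = c_1/(1+c_2)}, \eqn{Y = c_3/(1+c_2)} (projection centred on
#' `(0, 1, 0)`; the antipode `(0, -1, 0)` maps to infinity).
#'
#' @param c Unit 3-vector, or a 3-row/3-column matrix of such vectors.
#' @return Numeric `(X, Y)` pair (or 2-column matrix); `Inf` components
#'   signal the projection pole.
#' @export
stereographic_project <- function(c) {
  if (is.matrix(c)) {
    if (nrow(c) != 3 && ncol(c) == 3) c <- t(c)
    stopifnot(nrow(c) == 3)
    return(t(apply(c, 2, stereographic_project)))
  }
  c <- as.numeric(c)
  if (length(c) != 3) stop("stereographic projection requires N = 3", call. = FALSE)
  den <- 1 + c[2]
  if (abs(den) < 1e-14) return(c(X = Inf, Y = Inf))
  c(X = c[1] / den, Y = c[3] / den)
}

#' @rdname stereographic_project
#' @param X,Y Plane coordinates.
#' @return `stereographic_unproject()` returns the unit 3-vector mapping to
#'   `(X, Y)`.
#' @export
stereographic_unproject <- function(X, Y) {
  den <- 1 + X^2 + Y^2
  unname(c(2 * X / den, (1 - X^2 - Y^2) / den, 2 * Y / den))
}

# ---- internal checks -------------------------------------------------------

check_state <- function(c, H, norm_tol = 1e-8) {
  if (length(c) != nrow(H) || nrow(H) != ncol(H)) {
    stop("dimension mismatch between state vector and Hamiltonian", call. = FALSE)
  }
  dev <- abs(sqrt(sum(c^2)) - 1)
  if (dev > norm_tol) {
    stop("state vector is not normalized (|norm - 1| = ", format(dev), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

check_frame <- function(frame, c, tol = 1e-8) {
  if (!inherits(frame, "tangent_frame")) {
    stop("`frame` must be a tangent_frame object", call. = FALSE)
  }
  if (max(abs(frame$point - c / sqrt(sum(c^2)))) > tol) {
    stop("tangent frame was built at a different point", call. = FALSE)
  }
  invisible(TRUE)
}
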