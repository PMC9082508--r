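# Closed-shell and open-shell CSF vectors of the rotated orbital pair
#   psi_1 = cos(phi) sigma_g + sin(phi) sigma_u
#   psi_2 = -sin(phi) sigma_g + cos(phi) sigma_u
# expanded in the fixed {sigma_g^2, open-shell singlet, sigma_u^2} basis.
u_closed <- function(phi) {
  rbind(cos(phi)^2, sqrt(2) * cos(phi) * sin(phi), sin(phi)^2)
}
u_closed_d1 <- function(phi) {
  rbind(-sin(2 * phi), sqrt(2) * cos(2 * phi), sin(2 * phi))
}
u_closed_d2 <- function(phi) {
  rbind(-2 * cos(2 * phi), -2 * sqrt(2) * sin(2 * phi), 2 * cos(2 * phi))
}
u_open <- function(phi) {
  rbind(-sin(2 * phi) / sqrt(2), cos(2 * phi), sin(2 * phi) / sqrt(2))
}
u_open_d1 <- function(phi) {
  rbind(-sqrt(2) * cos(2 * phi), -2 * sin(2 * phi), sqrt(2) * cos(2 * phi))
}
u_open_d2 <- function(phi) {
  rbind(2 * sqrt(2) * sin(2 * phi), -4 * cos(2 * phi), -2 * sqrt(2) * sin(2 * phi))
}

#' Ansatz submanifolds of the H2 singlet hypersphere
#'
#' Constructs a parametric embedding `t -> c(t)` of an approximate-ansatz
#' wave function into the three-dimensional singlet hypersphere of
#' minimal-basis H2, together with its exact first and second derivatives.
#'
#' `rhf_embedding()` is the one-parameter family of closed-shell restricted
#' Hartree-Fock determinants: the doubly occupied orbital
#' \eqn{\psi_1 = \cos\phi\,\sigma_g + \sin\phi\,\sigma_u} gives the CSF
#' coefficient vector
#' \eqn{c(\phi) = (\cos^2\phi,\ \sqrt2\cos\phi\sin\phi,\ \sin^2\phi)},
#' periodic with period \eqn{\pi}.
#'
#' `esmf_embedding()` is the two-parameter excited-state mean-field family:
#' the reference determinant of \eqn{\psi_1} is mixed with the open-shell
#' singlet of the rotated pair \eqn{(\psi_1, \psi_2)} by a CI angle,
#' \eqn{c(\theta,\phi) = \cos\theta\,c_{\rm ref}(\phi) +
#' \sin\theta\,c_{\rm os}(\phi)}. At \eqn{\theta = 0} it reduces to the RHF
#' family. The fundamental domain is
#' \eqn{\theta \in [0, 2\pi) \times \phi \in [0, \pi)}, with
#' \eqn{\theta \to \theta + \pi} giving the overall-sign copy of the state.
#'
#' The trigonometric construction keeps the normalization constraint exact,
#' so ordinary parameter derivatives of \eqn{c^T H c} are the constrained
#' derivatives on the sphere.
#'
#' @return An object of class `ansatz_embedding`: list with fields
#'   `ansatz`, `parameter_names`, `periods`, and functions `map(t)`
#'   (3-vector, or 3 x m matrix for a matrix of parameter columns),
#'   `jacobian(t)` (3 x p), `second_derivatives(t)` (3 x p x p array).
#' @examples
#' emb <- rhf_embedding()
#' emb$map(0)        # the sigma_g^2 configuration
#' @export
rhf_embedding <- function() {
  structure(
    list(
      ansatz = "rhf",
      parameter_names = "phi",
      periods = pi,
      map = function(t) {
        if (is.matrix(t)) u_closed(t[1, ]) else drop(u_closed(t[1]))
      },
      jacobian = function(t) u_closed_d1(t[1]),
      second_derivatives = function(t) {
        array(u_closed_d2(t[1]), dim = c(3, 1, 1))
      }
    ),
    class = "ansatz_embedding"
  )
}

#' @rdname rhf_embedding
#' @export
esmf_embedding <- function() {
  structure(
    list(
      ansatz = "esmf",
      parameter_names = c("theta", "phi"),
      periods = c(2 * pi, pi),
      map = function(t) {
        if (is.matrix(t)) {
          th <- t[1, ]; ph <- t[2, ]
          sweep(u_closed(ph), 2, cos(th), `*`) +
            sweep(u_open(ph), 2, sin(th), `*`)
        } else {
          drop(cos(t[1]) * u_closed(t[2]) + sin(t[1]) * u_open(t[2]))
        }
      },
      jacobian = function(t) {
        th <- t[1]; ph <- t[2]
        cbind(
          -sin(th) * u_closed(ph) + cos(th) * u_open(ph),
          cos(th) * u_closed_d1(ph) + sin(th) * u_open_d1(ph)
        )
      },
      second_derivatives = function(t) {
        th <- t[1]; ph <- t[2]
        d <- array(0, dim = c(3, 2, 2))
        d[, 1, 1] <- -(cos(th) * u_closed(ph) + sin(th) * u_open(ph))
        d[, 1, 2] <- d[, 2, 1] <-
          -sin(th) * u_closed_d1(ph) + cos(th) * u_open_d1(ph)
        d[, 2, 2] <- cos(th) * u_closed_d2(ph) + sin(th) * u_open_d2(ph)
        d
      }
    ),
    class = "ansatz_embedding"
  )
}

#' @export
print.ansatz_embedding <- function(x, ...) {
  cat("Ansatz embedding:", toupper(x$ansatz),
      "(", length(x$parameter_names), "parameter(s):",
      paste(x$parameter_names, collapse = ", "), ")\n")
  invisible(x)
}
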