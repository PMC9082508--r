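#' Contracted s-type Gaussian shell
#'
#' Bundles the primitive exponents and contraction coefficients of a single
#' contracted s-type Gaussian basis function centred at a point in space.
#' Primitives are individually normalized and the contraction is rescaled so
#' that the self-overlap of the contracted function is exactly 1.
#'
#' @param center Numeric 3-vector, position in bohr.
#' @param exponents Positive numeric vector of primitive exponents (bohr^-2).
#' @param coefficients Numeric vector of contraction coefficients (same
#'   length as `exponents`), referring to normalized primitives.
#' @return An object of class `gaussian_shell` with fields `center`,
#'   `exponents` and `coefficients`; the stored coefficients absorb the
#'   primitive normalization constants and the overall contraction
#'   normalization.
#' @seealso [sto3g_hydrogen()] for the built-in hydrogen shell.
#' @export
gaussian_shell <- function(center, exponents, coefficients) {
  center <- as.numeric(center)
  exponents <- as.numeric(exponents)
  coefficients <- as.numeric(coefficients)
  if (length(center) != 3L) stop("`center` must be a 3-vector", call. = FALSE)
  if (length(exponents) != length(coefficients)) {
    stop("`exponents` and `coefficients` must have equal length", call. = FALSE)
  }
  if (any(exponents <= 0)) stop("primitive exponents must be positive", call. = FALSE)
  # absorb primitive norms, then normalize the contraction
  d <- coefficients * (2 * exponents / pi)^0.75
  self <- prim_pair_sum(exponents, d, exponents, d, 0, overlap_ss)
  d <- d / sqrt(self)
  structure(
    list(center = center, exponents = exponents, coefficients = d),
    class = "gaussian_shell"
  )
}

#' @export
print.gaussian_shell <- function(x, ...) {
  cat("Contracted s-type Gaussian shell (", length(x$exponents),
      " primitives)\n", sep = "")
  cat("  center (bohr):", format(x$center), "\n")
  cat("  exponents    :", format(x$exponents), "\n")
  invisible(x)
}

#' STO-3G hydrogen shell
#'
#' The canonical STO-3G three-Gaussian fit to a 1s Slater function
#' (Hehre, Stewart & Pople, J. Chem. Phys. 51, 2657 (1969)), with the
#' standard hydrogen scale factor applied to the exponents
#' (exponents scale as zeta^2).
#'
#' @param center Numeric 3-vector, position in bohr.
#' @param zeta Slater orbital exponent; the standard molecular-environment
#'   value for hydrogen is 1.24.
#' @return A [gaussian_shell()] object.
#' @export
sto3g_hydrogen <- function(center = c(0, 0, 0), zeta = 1.24) {
  # STO-3G 1s expansion for zeta = 1 (Hehre, Stewart & Pople 1969)
  alpha0 <- c(2.227660584, 0.405771156, 0.109818)
  d0     <- c(0.154328967, 0.535328142, 0.444634542)
  gaussian_shell(center, alpha0 * zeta^2, d0)
}

# ---- closed-form primitive integrals (s functions, normalized primitives
#      already folded into contraction coefficients) -------------------------

overlap_ss <- function(a, b, R2, ...) {
  p <- a + b
  (pi / p)^1.5 * exp(-a * b / p * R2)
}

kinetic_ss <- function(a, b, R2, ...) {
  p <- a + b
  mu <- a * b / p
  mu * (3 - 2 * mu * R2) * (pi / p)^1.5 * exp(-mu * R2)
}

# attraction to a unit positive charge at C; A, B are primitive centers
attraction_ss <- function(a, b, R2, A, B, C) {
  p <- a + b
  P <- (a * A + b * B) / p
  -(2 * pi / p) * exp(-a * b / p * R2) * boys_f0(p * sum((P - C)^2))
}

# generic double loop over primitive pairs of two shells
prim_pair_sum <- function(ea, da, eb, db, R2, f, ...) {
  acc <- 0
  for (i in seq_along(ea)) {
    for (j in seq_along(eb)) {
      acc <- acc + da[i] * db[j] * f(ea[i], eb[j], R2, ...)
    }
  }
  acc
}

# (ab|cd) over four s primitives in chemists' notation
eri_ssss <- function(a, b, c, d, A, B, C, D) {
  p <- a + b
  q <- c + d
  P <- (a * A + b * B) / p
  Q <- (c * C + d * D) / q
  2 * pi^2.5 / (p * q * sqrt(p + q)) *
    exp(-a * b / p * sum((A - B)^2) - c * d / q * sum((C - D)^2)) *
    boys_f0(p * q / (p + q) * sum((P - Q)^2))
}

#' Atomic-orbital integrals for H2 in a minimal s-type basis
#'
#' Evaluates the overlap, kinetic-energy, nuclear-attraction and two-electron
#' repulsion integrals for two identical contracted s-type shells placed on
#' two protons a bond length `R` apart, using the Gaussian product theorem
#' and the Boys function. All quantities are in atomic units (hartree, bohr).
#'
#' @param R Bond length in bohr (must be positive).
#' @param shell A [gaussian_shell()] describing the basis function carried by
#'   each atom; its `center` field is ignored (atoms sit at `(0,0,0)` and
#'   `(0,0,R)`). Defaults to [sto3g_hydrogen()].
#' @return An object of class `ao_integrals`: a list with fields
#'   `bond_length`, `overlap` (2x2), `kinetic` (2x2), `nuclear_attraction`
#'   (2x2), `eri` (2x2x2x2, chemists' notation `(ij|kl)`, 8-fold
#'   permutational symmetry) and `nuclear_repulsion` (`1/R`).
#' @examples
#' ints <- build_ao_integrals(1.4)
#' ints$overlap
#' @export
build_ao_integrals <- function(R, shell = sto3g_hydrogen()) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0) {
    stop("bond length `R` must be a single positive number (bohr)", call. = FALSE)
  }
  if (!inherits(shell, "gaussian_shell")) {
    stop("`shell` must be a gaussian_shell object", call. = FALSE)
  }
  ea <- shell$exponents
  da <- shell$coefficients
  centers <- list(c(0, 0, 0), c(0, 0, R))

  S <- matrix(0, 2, 2)
  Tm <- matrix(0, 2, 2)
  V <- matrix(0, 2, 2)
  for (i in 1:2) {
    for (j in i:2) {
      A <- centers[[i]]; B <- centers[[j]]
      R2 <- sum((A - B)^2)
      S[i, j] <- prim_pair_sum(ea, da, ea, da, R2, overlap_ss)
      Tm[i, j] <- prim_pair_sum(ea, da, ea, da, R2, kinetic_ss)
      v <- 0
      for (Cc in centers) {
        v <- v + prim_pair_sum(ea, da, ea, da, R2, attraction_ss,
                               A = A, B = B, C = Cc)
      }
      V[i, j] <- v
      S[j, i] <- S[i, j]; Tm[j, i] <- Tm[i, j]; V[j, i] <- V[i, j]
    }
  }

  eri <- array(0, c(2, 2, 2, 2))
  np <- length(ea)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
    A <- centers[[i]]; B <- centers[[j]]
    C <- centers[[k]]; D <- centers[[l]]
    acc <- 0
    for (p in seq_len(np)) for (q in seq_len(np)) {
      for (r in seq_len(np)) for (s in seq_len(np)) {
        acc <- acc + da[p] * da[q] * da[r] * da[s] *
          eri_ssss(ea[p], ea[q], ea[r], ea[s], A, B, C, D)
      }
    }
    eri[i, j, k, l] <- acc
  }

  structure(
    list(bond_length = R,
         overlap = S,
         kinetic = Tm,
         nuclear_attraction = V,
         eri = eri,
         nuclear_repulsion = 1 / R),
    class = "ao_integrals"
  )
}

#' @export
print.ao_integrals <- function(x, ...) {
  cat("AO integral set for H2, R =", x$bond_length, "bohr\n")
  cat("  S12 =", x$overlap[1, 2],
      " (11|11) =", x$eri[1, 1, 1, 1],
      " Vnn =", x$nuclear_repulsion, "\n")
  invisible(x)
}
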