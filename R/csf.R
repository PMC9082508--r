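#' Symmetry-adapted molecular orbitals for H2
#'
#' Builds the gerade/ungerade molecular orbitals
#' \eqn{\sigma_g = (\chi_1+\chi_2)/\sqrt{2(1+S_{12})}} and
#' \eqn{\sigma_u = (\chi_1-\chi_2)/\sqrt{2(1-S_{12})}} from the AO overlap.
#' The phase convention (equal-sign coefficients for \eqn{\sigma_g},
#' first-coefficient-positive for \eqn{\sigma_u}) is fixed here once; all
#' downstream configuration-state-function coordinates depend on it.
#'
#' @param ints An `ao_integrals` object from [build_ao_integrals()].
#' @return An object of class `mo_basis`: list with `mo_coeffs` (2x2 matrix,
#'   columns = \eqn{\sigma_g}, \eqn{\sigma_u} in the AO basis) and `labels`.
#' @export
symmetry_mos <- function(ints) {
  if (!inherits(ints, "ao_integrals")) {
    stop("`ints` must be an ao_integrals object", call. = FALSE)
  }
  s12 <- ints$overlap[1, 2]
  if (abs(s12) >= 1) {
    stop("|S12| >= 1: basis functions are linearly dependent", call. = FALSE)
  }
  ng <- 1 / sqrt(2 * (1 + s12))
  nu <- 1 / sqrt(2 * (1 - s12))
  C <- cbind(c(ng, ng), c(nu, -nu))
  colnames(C) <- c("sigma_g", "sigma_u")
  structure(list(mo_coeffs = C, labels = c("gerade", "ungerade")),
            class = "mo_basis")
}

# one- and two-electron integrals in the sigma_g/sigma_u MO basis
mo_integrals <- function(ints, mos = symmetry_mos(ints)) {
  C <- mos$mo_coeffs
  h_ao <- ints$kinetic + ints$nuclear_attraction
  h <- t(C) %*% h_ao %*% C
  g <- array(0, c(2, 2, 2, 2))
  for (p in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
    acc <- 0
    for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
      acc <- acc + C[i, p] * C[j, q] * C[k, r] * C[l, s] * ints$eri[i, j, k, l]
    }
    g[p, q, r, s] <- acc
  }
  list(h = h, eri = g)
}

#' Singlet CSF Hamiltonian for minimal-basis H2
#'
#' Assembles the 3x3 real symmetric Hamiltonian of the two-electron singlet
#' problem in the configuration-state-function basis
#' \eqn{\{\sigma_g^2,\ (|\sigma_g\bar\sigma_u\rangle +
#' |\sigma_u\bar\sigma_g\rangle)/\sqrt 2,\ \sigma_u^2\}} via the
#' Slater-Condon rules, with the nuclear repulsion \eqn{1/R} added to the
#' diagonal so that landscape energies are total energies. The open-shell
#' singlet has ungerade spatial symmetry, so its coupling to both
#' closed-shell (gerade) configurations vanishes identically; the only
#' off-diagonal element is the exchange integral
#' \eqn{(\sigma_g\sigma_u|\sigma_g\sigma_u)} coupling the two closed shells.
#'
#' @param R Bond length in bohr.
#' @param shell Basis shell per atom; defaults to [sto3g_hydrogen()].
#' @return An object of class `csf_hamiltonian`: list with `matrix` (3x3,
#'   hartree), `basis_order`, `bond_length`.
#' @examples
#' H <- build_csf_hamiltonian(1.437707)
#' eigen(H$matrix, symmetric = TRUE)$values  # the three exact singlet energies
#' @export
build_csf_hamiltonian <- function(R, shell = sto3g_hydrogen()) {
  ints <- build_ao_integrals(R, shell)
  mo <- mo_integrals(ints)
  h <- mo$h
  g <- mo$eri
  Jg  <- g[1, 1, 1, 1]
  Ju  <- g[2, 2, 2, 2]
  Jgu <- g[1, 1, 2, 2]
  Kgu <- g[1, 2, 1, 2]
  M <- matrix(0, 3, 3)
  M[1, 1] <- 2 * h[1, 1] + Jg
  M[2, 2] <- h[1, 1] + h[2, 2] + Jgu + Kgu
  M[3, 3] <- 2 * h[2, 2] + Ju
  M[1, 3] <- M[3, 1] <- Kgu
  M <- M + diag(3) * ints$nuclear_repulsion
  basis <- c("sigma_g^2", "open-shell singlet", "sigma_u^2")
  dimnames(M) <- list(basis, basis)
  structure(list(matrix = M, basis_order = basis, bond_length = R),
            class = "csf_hamiltonian")
}

#' @export
print.csf_hamiltonian <- function(x, digits = 6, ...) {
  cat("Singlet CSF Hamiltonian, H2/STO-3G, R =", x$bond_length, "bohr\n")
  print(round(x$matrix, digits))
  cat("eigenvalues (hartree):",
      format(eigen(x$matrix, symmetric = TRUE)$values, digits = digits), "\n")
  invisible(x)
}

#' Write / read a Hamiltonian matrix
#'
#' Lossless exchange of a real symmetric Hamiltonian as JSON
#' (`{basis_order, bond_length, matrix}` with the matrix stored row-major)
#' or as plain whitespace-delimited text (one row per line). Doubles are
#' serialized at full precision.
#'
#' @param x A `csf_hamiltonian` or a plain symmetric matrix.
#' @param path Output (input) file path.
#' @param format `"json"` or `"csv"` (delimited text).
#' @return `write_hamiltonian()` returns `path` invisibly;
#'   `read_hamiltonian()` returns a `csf_hamiltonian`-like list (fields
#'   `matrix`, `basis_order`, `bond_length`; the latter two are `NULL` for
#'   delimited text or generic matrices).
#' @export
write_hamiltonian <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(x, "csf_hamiltonian")) {
    M <- x$matrix; basis <- x$basis_order; R <- x$bond_length
  } else {
    M <- as.matrix(x); basis <- NULL; R <- NULL
    check_symmetric(M)
  }
  if (format == "json") {
    obj <- list(basis_order = basis, bond_length = R,
                dimension = nrow(M), matrix = as.vector(t(M)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
  } else {
    lines <- apply(M, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_hamiltonian
#' @export
read_hamiltonian <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    n <- obj$dimension
    M <- matrix(as.numeric(obj$matrix), n, n, byrow = TRUE)
    basis <- obj$basis_order
    R <- obj$bond_length
  } else {
    rows <- strsplit(trimws(readLines(path)), "[,[:space:]]+")
    rows <- rows[vapply(rows, length, 1L) > 0]
    M <- do.call(rbind, lapply(rows, as.numeric))
    basis <- NULL
    R <- NULL
  }
  check_symmetric(M)
  out <- list(matrix = M, basis_order = basis, bond_length = R)
  if (!is.null(basis)) class(out) <- "csf_hamiltonian"
  out
}

check_symmetric <- function(M, tol = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M) ||
      max(abs(M - t(M))) > tol * max(1, max(abs(M)))) {
    stop("Hamiltonian must be a real symmetric square matrix", call. = FALSE)
  }
  invisible(M)
}
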