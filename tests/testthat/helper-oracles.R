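# Independent numerical oracles used to pin the closed-form integral engine.
#
# The pair-integral reduction: for spherically symmetric factors f(|r - A|)
# and g(|r - B|) with D = |A - B| > 0 (bipolar coordinates),
#   int f(|r-A|) g(|r-B|) d3r = (2 pi / D) int_0^inf s f(s) G(|D-s|, D+s) ds
# with G(u, v) = int_u^v t g(t) dt.  The Coulomb potential of a Gaussian
# charge comes from the shell theorem.  None of this shares the
# Boys-function route used by the package.

erf_oracle <- function(x) 2 * pnorm(x * sqrt(2)) - 1

radial_pair <- function(f, Gfun, D, rel.tol = 1e-11) {
  if (D < 1e-12) stop("use the concentric formula for D = 0")
  val <- integrate(function(s) {
    2 * pi / D * s * f(s) * Gfun(abs(D - s), D + s)
  }, 0, Inf, rel.tol = rel.tol, subdivisions = 400L)
  val$value
}

concentric <- function(fg, rel.tol = 1e-11) {
  4 * pi * integrate(function(s) s^2 * fg(s), 0, Inf,
                     rel.tol = rel.tol, subdivisions = 400L)$value
}

# overlap of contracted s shells at distance D (D > 0) or same center (D = 0)
oracle_overlap <- function(shell, D) {
  e <- shell$exponents; d <- shell$coefficients
  acc <- 0
  for (i in seq_along(e)) for (j in seq_along(e)) {
    a <- e[i]; b <- e[j]
    acc <- acc + d[i] * d[j] * if (D == 0) {
      concentric(function(s) exp(-(a + b) * s^2))
    } else {
      radial_pair(function(s) exp(-a * s^2),
                  function(u, v) (exp(-b * u^2) - exp(-b * v^2)) / (2 * b), D)
    }
  }
  acc
}

# kinetic energy: -(1/2) Lap e^{-b t^2} = (3b - 2 b^2 t^2) e^{-b t^2};
# antiderivative of t (3b - 2b^2 t^2) e^{-b t^2} is e^{-b t^2} (b t^2 - 1/2)
oracle_kinetic <- function(shell, D) {
  e <- shell$exponents; d <- shell$coefficients
  acc <- 0
  for (i in seq_along(e)) for (j in seq_along(e)) {
    a <- e[i]; b <- e[j]
    acc <- acc + d[i] * d[j] * if (D == 0) {
      concentric(function(s) exp(-a * s^2) * (3 * b - 2 * b^2 * s^2) * exp(-b * s^2))
    } else {
      A <- function(t) exp(-b * t^2) * (b * t^2 - 0.5)
      radial_pair(function(s) exp(-a * s^2),
                  function(u, v) A(v) - A(u), D)
    }
  }
  acc
}

# <chi_i | 1/|r - C| | chi_j> for shells at centers with separation R,
# nucleus at one of the two centers. `di`, `dj`: distance of each shell
# center from the nucleus (0 or R).
oracle_attraction_element <- function(shell, R, di, dj) {
  e <- shell$exponents; d <- shell$coefficients
  acc <- 0
  for (i in seq_along(e)) for (j in seq_along(e)) {
    a <- e[i]; b <- e[j]
    val <- if (di == 0 && dj == 0) {
      concentric(function(s) exp(-(a + b) * s^2) / s)
    } else if (di == dj) {
      # both shells sit on the same center, nucleus at distance di
      p <- a + b
      radial_pair(function(s) exp(-p * s^2),
                  function(u, v) v - u, di)     # g(t) = 1/t
    } else if (dj == 0) {
      # shell j on the nucleus: g(t) = e^{-b t^2} / t around C = B
      radial_pair(function(s) exp(-a * s^2),
                  function(u, v) sqrt(pi / b) / 2 *
                    (erf_oracle(sqrt(b) * v) - erf_oracle(sqrt(b) * u)), R)
    } else {
      # shell i on the nucleus: swap roles
      radial_pair(function(s) exp(-b * s^2),
                  function(u, v) sqrt(pi / a) / 2 *
                    (erf_oracle(sqrt(a) * v) - erf_oracle(sqrt(a) * u)), R)
    }
    acc <- acc + d[i] * d[j] * val
  }
  acc
}

# electron repulsion (ij|kl) over contracted shells on two centers at
# separation R; `ci` etc. give each shell's center (1 or 2). Charge
# distribution 2 is collapsed to a single Gaussian by completing the square;
# its Coulomb potential Phi(t) = (pi/q)^{3/2} erf(sqrt(q) t)/t follows from
# the shell theorem, and the final 3D integral is done by radial quadrature.
oracle_eri_element <- function(shell, R, ci, cj, ck, cl) {
  e <- shell$exponents; d <- shell$coefficients
  pos <- c(0, R)
  acc <- 0
  for (i in seq_along(e)) for (j in seq_along(e)) {
    for (k in seq_along(e)) for (l in seq_along(e)) {
      a <- e[i]; b <- e[j]; g <- e[k]; h <- e[l]
      p <- a + b; q <- g + h
      P <- (a * pos[ci] + b * pos[cj]) / p
      Q <- (g * pos[ck] + h * pos[cl]) / q
      Kab <- exp(-a * b / p * (pos[ci] - pos[cj])^2)
      Kcd <- exp(-g * h / q * (pos[ck] - pos[cl])^2)
      D <- abs(P - Q)
      GPhi <- function(u, v) {
        # int t Phi_q(t) dt with Phi_q(t) = (pi/q)^{3/2} erf(sqrt(q) t)/t
        (pi / q)^1.5 * ((v * erf_oracle(sqrt(q) * v) + exp(-q * v^2) / sqrt(pi * q)) -
                        (u * erf_oracle(sqrt(q) * u) + exp(-q * u^2) / sqrt(pi * q)))
      }
      val <- if (D < 1e-12) {
        concentric(function(s) exp(-p * s^2) * (pi / q)^1.5 *
                     erf_oracle(sqrt(q) * s) / s)
      } else {
        radial_pair(function(s) exp(-p * s^2), GPhi, D)
      }
      acc <- acc + d[i] * d[j] * d[k] * d[l] * Kab * Kcd * val
    }
  }
  acc
}

# 4x4 Hamiltonian in the Ms = 0 Slater-determinant basis
# {|g gbar|, |g ubar|, |u gbar|, |u ubar|} via the Slater-Condon rules;
# an independent construction route for the singlet spectrum (the fourth
# eigenvalue is the Ms = 0 triplet).
determinant_hamiltonian <- function(R) {
  ints <- build_ao_integrals(R)
  mos <- symmetry_mos(ints)
  C <- mos$mo_coeffs
  h <- t(C) %*% (ints$kinetic + ints$nuclear_attraction) %*% C
  g <- array(0, c(2, 2, 2, 2))
  for (p in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
    acc <- 0
    for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
      acc <- acc + C[i, p] * C[j, q] * C[k, r] * C[l, s] * ints$eri[i, j, k, l]
    }
    g[p, q, r, s] <- acc
  }
  M <- matrix(0, 4, 4)
  M[1, 1] <- 2 * h[1, 1] + g[1, 1, 1, 1]
  M[2, 2] <- h[1, 1] + h[2, 2] + g[1, 1, 2, 2]
  M[3, 3] <- M[2, 2]
  M[4, 4] <- 2 * h[2, 2] + g[2, 2, 2, 2]
  # single substitutions (vanish by g/u symmetry, kept as computed values)
  M[1, 2] <- M[2, 1] <- h[1, 2] + g[1, 2, 1, 1]
  M[1, 3] <- M[3, 1] <- h[1, 2] + g[1, 2, 1, 1]
  M[2, 4] <- M[4, 2] <- h[1, 2] + g[1, 2, 2, 2]
  M[3, 4] <- M[4, 3] <- h[1, 2] + g[1, 2, 2, 2]
  # double substitutions
  M[1, 4] <- M[4, 1] <- g[1, 2, 1, 2]
  M[2, 3] <- M[3, 2] <- g[1, 2, 1, 2]
  M + diag(4) / R
}

# ---- finite-difference utilities ------------------------------------------

# directional derivative of the energy along a unit tangent vector, stepping
# on the sphere along the geodesic c(h) = cos(h) c + sin(h) d
fd_geodesic_d1 <- function(c, d, H, h = 1e-6) {
  Ep <- state_energy(cos(h) * c + sin(h) * d, H)
  Em <- state_energy(cos(h) * c - sin(h) * d, H)
  (Ep - Em) / (2 * h)
}

fd_geodesic_d2 <- function(c, d, H, h = 1e-4) {
  Ep <- state_energy(cos(h) * c + sin(h) * d, H)
  Em <- state_energy(cos(h) * c - sin(h) * d, H)
  E0 <- state_energy(c, H)
  (Ep + Em - 2 * E0) / h^2
}

# central finite-difference gradient of a scalar function of parameters
fd_param_grad <- function(f, t, h = 1e-6) {
  vapply(seq_along(t), function(a) {
    tp <- t; tm <- t
    tp[a] <- tp[a] + h
    tm[a] <- tm[a] - h
    (f(tp) - f(tm)) / (2 * h)
  }, 0)
}

fd_param_hess <- function(f, t, h = 1e-4) {
  p <- length(t)
  Hm <- matrix(0, p, p)
  shift <- function(t, a, da, b, db) {
    t[a] <- t[a] + da
    t[b] <- t[b] + db
    t
  }
  for (a in seq_len(p)) {
    tp <- t; tm <- t
    tp[a] <- tp[a] + h
    tm[a] <- tm[a] - h
    Hm[a, a] <- (f(tp) + f(tm) - 2 * f(t)) / h^2
    for (b in seq_len(p)) {
      if (b == a) next
      Hm[a, b] <- (f(shift(t, a, h, b, h)) - f(shift(t, a, h, b, -h)) -
                     f(shift(t, a, -h, b, h)) + f(shift(t, a, -h, b, -h))) /
        (4 * h^2)
    }
  }
  (Hm + t(Hm)) / 2
}

random_unit <- function(n) {
  v <- rnorm(n)
  v / sqrt(sum(v^2))
}
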