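# ---- ambient-space objective derivatives ----------------------------------
# Each objective is a smooth function of the embedded coefficient vector c;
# because the trigonometric embeddings keep |c| = 1 exactly, the chain rule
# through the map gives the constrained parameter-space derivatives directly.

ambient_value <- function(c, H, objective) {
  Hc <- drop(H %*% c)
  E <- sum(c * Hc)
  switch(objective,
    energy = E,
    variance = sum(Hc^2) - E^2,
    stop("unknown objective: ", objective, call. = FALSE)
  )
}

ambient_gradient <- function(c, H, objective) {
  Hc <- drop(H %*% c)
  switch(objective,
    energy = 2 * Hc,
    variance = {
      E <- sum(c * Hc)
      drop(2 * (H %*% Hc)) - 4 * E * Hc
    },
    stop("unknown objective: ", objective, call. = FALSE)
  )
}

ambient_hessian <- function(c, H, objective) {
  switch(objective,
    energy = 2 * H,
    variance = {
      Hc <- drop(H %*% c)
      E <- sum(c * Hc)
      2 * H %*% H - 4 * E * H - 8 * tcrossprod(Hc)
    },
    stop("unknown objective: ", objective, call. = FALSE)
  )
}

#' Objective value on an ansatz submanifold
#'
#' Evaluates the energy \eqn{c(t)^T H c(t)}, the Hamiltonian variance, or the
#' local square-gradient (the SGM objective, [sgm_objective()]) at parameters
#' `t` of an ansatz embedding.
#'
#' @param embedding An [rhf_embedding()] or [esmf_embedding()].
#' @param t Numeric parameter vector (radians).
#' @param H Real symmetric Hamiltonian (typically
#'   `build_csf_hamiltonian(R)$matrix`).
#' @param objective One of `"energy"`, `"variance"`,
#'   `"local_square_gradient"`.
#' @return Scalar objective value (hartree or hartree^2).
#' @export
ansatz_objective <- function(embedding, t, H,
                             objective = c("energy", "variance",
                                           "local_square_gradient")) {
  objective <- match.arg(objective)
  if (objective == "local_square_gradient") return(sgm_objective(embedding, t, H))
  ambient_value(embedding$map(t), H, objective)
}

#' Constrained gradient of an objective in parameter space
#'
#' For the energy this is \eqn{J^T (2 H c(t))}, the projection of the global
#' energy gradient onto the tangent vectors of the ansatz submanifold; an
#' optimized determinant satisfies the Brillouin condition when it vanishes.
#' Analytic expressions are used for all three objectives (the square-
#' gradient objective differentiates the composed form through the exact
#' second derivatives of the embedding).
#'
#' @inheritParams ansatz_objective
#' @return Numeric gradient of length `p` (the number of ansatz parameters).
#' @export
constrained_gradient <- function(embedding, t, H,
                                 objective = c("energy", "variance",
                                               "local_square_gradient")) {
  objective <- match.arg(objective)
  J <- embedding$jacobian(t)
  if (objective == "local_square_gradient") {
    c0 <- embedding$map(t)
    Hc <- drop(H %*% c0)
    g <- drop(crossprod(J, 2 * Hc))            # energy gradient
    D2 <- embedding$second_derivatives(t)
    p <- length(g)
    out <- numeric(p)
    for (b in seq_len(p)) {
      # d g_a / d t_b = 2 [ (d2c/dt_a dt_b)^T Hc + J_a^T H J_b ]
      dg <- 2 * (drop(crossprod(D2[, , b], Hc)) +
                   drop(crossprod(J, H %*% J[, b])))
      out[b] <- 2 * sum(g * dg)
    }
    return(out)
  }
  drop(crossprod(J, ambient_gradient(embedding$map(t), H, objective)))
}

#' Constrained Hessian of an objective in parameter space
#'
#' Exact second derivatives of the composed objective
#' \eqn{f(c(t))}: \eqn{J^T \nabla^2 f J + \sum_k (\nabla f)_k\,
#' \partial^2 c_k/\partial t\,\partial t}, using the analytic second
#' derivatives of the trigonometric embedding. The square-gradient objective
#' (which would require third derivatives of the map) uses central finite
#' differences of its analytic gradient with step `fd_step`.
#'
#' @inheritParams ansatz_objective
#' @param fd_step Finite-difference step for the square-gradient objective.
#' @return Symmetric `p` x `p` matrix.
#' @export
constrained_hessian <- function(embedding, t, H,
                                objective = c("energy", "variance",
                                              "local_square_gradient"),
                                fd_step = 1e-5) {
  objective <- match.arg(objective)
  p <- length(embedding$parameter_names)
  if (objective == "local_square_gradient") {
    Hm <- matrix(0, p, p)
    for (b in seq_len(p)) {
      tp <- t; tm <- t
      tp[b] <- tp[b] + fd_step
      tm[b] <- tm[b] - fd_step
      Hm[, b] <- (constrained_gradient(embedding, tp, H, objective) -
                    constrained_gradient(embedding, tm, H, objective)) /
        (2 * fd_step)
    }
    return((Hm + t(Hm)) / 2)
  }
  c0 <- embedding$map(t)
  J <- embedding$jacobian(t)
  D2 <- embedding$second_derivatives(t)
  gf <- ambient_gradient(c0, H, objective)
  Hf <- ambient_hessian(c0, H, objective)
  Hm <- crossprod(J, Hf %*% J)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    Hm[a, b] <- Hm[a, b] + sum(gf * D2[, a, b])
  }
  (Hm + t(Hm)) / 2
}

#' Square-gradient-minimization objective
#'
#' The squared norm of the ansatz-constrained energy gradient,
#' \eqn{|\tilde\nabla E|^2 = |J^T 2Hc|^2}. It is zero exactly at the
#' stationary points of the constrained energy, which distinguishes physical
#' solutions from variance-only artifacts (where the exact variance is
#' stationary on the submanifold but the constrained energy is not).
#'
#' @inheritParams ansatz_objective
#' @return Non-negative scalar (hartree^2).
#' @export
sgm_objective <- function(embedding, t, H) {
  g <- constrained_gradient(embedding, t, H, "energy")
  sum(g^2)
}

# ---- vectorized gradient over a parameter grid ----------------------------
# Tmat: p x M matrix of parameter columns. Returns p x M matrix of gradients.
grid_gradient <- function(embedding, Tmat, H, objective) {
  C <- embedding$map(Tmat)                    # 3 x M
  Jl <- jacobian_grid(embedding, Tmat)        # list of 3 x M, one per param
  p <- length(Jl)
  M <- ncol(C)
  HC <- H %*% C
  if (objective == "energy") {
    G <- 2 * HC
  } else if (objective == "variance") {
    E <- colSums(C * HC)
    G <- 2 * (H %*% HC) - 4 * HC * rep(E, each = nrow(C))
  } else { # local_square_gradient
    gpar <- matrix(0, p, M)
    for (a in seq_len(p)) gpar[a, ] <- 2 * colSums(Jl[[a]] * HC)
    D2l <- second_grid(embedding, Tmat)
    out <- matrix(0, p, M)
    for (b in seq_len(p)) {
      for (a in seq_len(p)) {
        dg_ab <- 2 * (colSums(D2l[[a]][[b]] * HC) +
                        colSums(Jl[[a]] * (H %*% Jl[[b]])))
        out[b, ] <- out[b, ] + 2 * gpar[a, ] * dg_ab
      }
    }
    return(out)
  }
  out <- matrix(0, p, M)
  for (a in seq_len(p)) out[a, ] <- colSums(Jl[[a]] * G)
  out
}

jacobian_grid <- function(embedding, Tmat) {
  if (embedding$ansatz == "rhf") {
    list(u_closed_d1(Tmat[1, ]))
  } else {
    th <- Tmat[1, ]; ph <- Tmat[2, ]
    cth <- rep(cos(th), each = 3); sth <- rep(sin(th), each = 3)
    list(
      -sth * u_closed(ph) + cth * u_open(ph),
      cth * u_closed_d1(ph) + sth * u_open_d1(ph)
    )
  }
}

second_grid <- function(embedding, Tmat) {
  if (embedding$ansatz == "rhf") {
    list(list(u_closed_d2(Tmat[1, ])))
  } else {
    th <- Tmat[1, ]; ph <- Tmat[2, ]
    cth <- rep(cos(th), each = 3); sth <- rep(sin(th), each = 3)
    d_tt <- -(cth * u_closed(ph) + sth * u_open(ph))
    d_tp <- -sth * u_closed_d1(ph) + cth * u_open_d1(ph)
    d_pp <- cth * u_closed_d2(ph) + sth * u_open_d2(ph)
    list(list(d_tt, d_tp), list(d_tp, d_pp))
  }
}

# ---- stationary-point search ----------------------------------------------

#' Find constrained stationary points on an ansatz submanifold
#'
#' Scans a dense periodic grid over the fundamental parameter domain for
#' candidate stationary points of the chosen objective (local minima of the
#' parameter-gradient norm over a full grid neighbourhood), polishes each
#' candidate with a damped Newton iteration on the gradient, removes
#' duplicates modulo periodicity and overall wave-function sign, and
#' classifies each survivor by the eigenvalue signature of its constrained
#' Hessian. The search is deterministic for a fixed grid.
#'
#' @inheritParams ansatz_objective
#' @param grid_density Grid points per parameter (>= 64; default 720).
#' @param stationary_tol Gradient-norm threshold for accepting a polished
#'   point.
#' @param index_tol Hessian eigenvalues within `index_tol` of zero are not
#'   counted as negative.
#' @param dedup_tol Two points are the same solution when their embedded
#'   3-vectors agree up to overall sign within this tolerance.
#' @return Object of class `constrained_stationary_points`: list of records
#'   with fields `parameters` (named, radians), `point` (embedded 3-vector),
#'   `objective`, `value`, `energy`, `hessian_index`,
#'   `hessian_eigenvalues`, `label`, `degeneracy_group`. Non-convergent
#'   candidates are dropped with a warning, never silently merged.
#'   `as.data.frame()` gives a tabular view.
#' @examples
#' H <- build_csf_hamiltonian(3)$matrix
#' find_stationary_points(rhf_embedding(), H, "energy")
#' @export
find_stationary_points <- function(embedding, H,
                                   objective = c("energy", "variance",
                                                 "local_square_gradient"),
                                   grid_density = 720,
                                   stationary_tol = 1e-9,
                                   index_tol = 1e-9,
                                   dedup_tol = 1e-6) {
  objective <- match.arg(objective)
  check_symmetric(H)
  if (grid_density < 64) stop("`grid_density` must be >= 64", call. = FALSE)
  p <- length(embedding$parameter_names)
  periods <- embedding$periods

  axes <- lapply(seq_len(p), function(a) {
    seq(0, periods[a], length.out = grid_density + 1)[seq_len(grid_density)]
  })
  if (p == 1L) {
    Tmat <- matrix(axes[[1]], nrow = 1)
  } else {
    gr <- expand.grid(axes[[1]], axes[[2]])
    Tmat <- rbind(gr[[1]], gr[[2]])
  }
  G <- grid_gradient(embedding, Tmat, H, objective)
  gn2 <- colSums(G^2)

  # candidate nodes: local minima of |grad|^2 over the periodic neighbourhood
  if (p == 1L) {
    v <- gn2
    cand <- which(v <= pmin(c(v[-1], v[1]), c(v[length(v)], v[-length(v)])))
  } else {
    m <- matrix(gn2, grid_density, grid_density)
    shifts <- expand.grid(di = -1:1, dj = -1:1)
    is_min <- matrix(TRUE, grid_density, grid_density)
    for (s in seq_len(nrow(shifts))) {
      di <- shifts$di[s]; dj <- shifts$dj[s]
      if (di == 0 && dj == 0) next
      nb <- m[(seq_len(grid_density) - 1 + di) %% grid_density + 1,
              (seq_len(grid_density) - 1 + dj) %% grid_density + 1]
      is_min <- is_min & (m <= nb)
    }
    cand <- which(as.vector(is_min))
  }

  records <- list()
  n_failed <- 0L
  for (k in cand) {
    t0 <- Tmat[, k]
    res <- newton_polish(embedding, t0, H, objective, stationary_tol)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    v <- embedding$map(res$t)
    dup <- FALSE
    for (r in records) {
      if (min(sqrt(sum((v - r$point)^2)), sqrt(sum((v + r$point)^2))) < dedup_tol) {
        dup <- TRUE
        break
      }
    }
    if (dup) next
    Hm <- constrained_hessian(embedding, res$t, H, objective)
    lam <- sort(eigen(Hm, symmetric = TRUE, only.values = TRUE)$values)
    idx <- sum(lam < -index_tol)
    label <- if (idx == 0 && all(lam > index_tol)) "minimum"
      else if (idx == p && p > 0 && all(lam < -index_tol)) "maximum"
      else if (idx == 0) "degenerate minimum"
      else paste0("index-", idx, " saddle")
    tc <- canonicalize_parameters(res$t, periods)
    names(tc) <- embedding$parameter_names
    records[[length(records) + 1L]] <- list(
      parameters = tc,
      point = v,
      objective = objective,
      value = ansatz_objective(embedding, res$t, H, objective),
      energy = ambient_value(v, H, "energy"),
      hessian_index = idx,
      hessian_eigenvalues = lam,
      label = label
    )
  }
  if (n_failed > 0L) {
    warning(n_failed, " candidate point(s) dropped: Newton polish did not converge",
            call. = FALSE)
  }
  # degeneracy groups: solutions sharing both objective value and energy
  vals <- vapply(records, `[[`, 0, "value")
  ens <- vapply(records, `[[`, 0, "energy")
  grp <- integer(length(records))
  gid <- 0L
  for (i in seq_along(records)) {
    if (grp[i] == 0L) {
      gid <- gid + 1L
      grp[abs(vals - vals[i]) < 1e-8 & abs(ens - ens[i]) < 1e-8] <- gid
    }
  }
  for (i in seq_along(records)) records[[i]]$degeneracy_group <- grp[i]
  ord <- order(vapply(records, `[[`, 0, "energy"))
  structure(records[ord], class = "constrained_stationary_points",
            ansatz = embedding$ansatz, objective = objective)
}

# damped Newton iteration on the objective gradient; NULL when not converged
newton_polish <- function(embedding, t0, H, objective, tol, maxit = 60L) {
  t <- t0
  for (it in seq_len(maxit)) {
    g <- constrained_gradient(embedding, t, H, objective)
    if (sqrt(sum(g^2)) < tol * 1e-3 && it > 1L) break
    Hm <- constrained_hessian(embedding, t, H, objective)
    step <- tryCatch(solve(Hm, -g), error = function(e) NULL)
    if (is.null(step)) {
      # singular Hessian: fall back to a small gradient step
      step <- -g
    }
    sn <- sqrt(sum(step^2))
    if (sn > 0.2) step <- step * (0.2 / sn)
    t <- t + step
    if (sqrt(sum(step^2)) < 1e-14) break
  }
  g <- constrained_gradient(embedding, t, H, objective)
  if (sqrt(sum(g^2)) < tol) list(t = t, grad_norm = sqrt(sum(g^2))) else NULL
}

# reduce parameters into the fundamental domain; for the 2-parameter ansatz
# fold theta into (-pi/2, pi/2] using the overall-sign copy theta -> theta - pi
canonicalize_parameters <- function(t, periods) {
  t <- ((t %% periods) + periods) %% periods
  if (length(t) == 2L) {
    if (t[1] > pi) t[1] <- t[1] - 2 * pi          # theta in (-pi, pi]
    if (t[1] > pi / 2) t[1] <- t[1] - pi          # sign copy
    if (t[1] <= -pi / 2) t[1] <- t[1] + pi
    if (t[2] > pi / 2) t[2] <- t[2] - pi          # phi in (-pi/2, pi/2]
  }
  t
}

#' @export
as.data.frame.constrained_stationary_points <- function(x, ...) {
  pn <- names(x[[1]]$parameters)
  out <- data.frame(
    energy = vapply(x, `[[`, 0, "energy"),
    value = vapply(x, `[[`, 0, "value"),
    hessian_index = vapply(x, `[[`, 0L, "hessian_index"),
    label = vapply(x, `[[`, "", "label"),
    degeneracy_group = vapply(x, `[[`, 0L, "degeneracy_group")
  )
  for (i in seq_along(pn)) {
    out[[pn[i]]] <- vapply(x, function(r) r$parameters[[i]], 0)
  }
  out[, c(pn, setdiff(names(out), pn)), drop = FALSE]
}

#' @export
print.constrained_stationary_points <- function(x, ...) {
  cat("Constrained stationary points (", attr(x, "ansatz"), " ansatz, ",
      attr(x, "objective"), " objective): ", length(x), " solution(s)\n",
      sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' Track stationary-point branches across bond lengths
#'
#' Runs [find_stationary_points()] for a series of bond lengths of the
#' built-in H2 model and links solutions between consecutive geometries by
#' nearest embedded-state matching (up to overall sign). Branches that
#' appear or disappear (Coulson-Fischer-type events) are reported via
#' `message()`, never as errors.
#'
#' @inheritParams find_stationary_points
#' @param R_values Numeric vector of bond lengths in bohr (within
#'   `[0.8, 10]`).
#' @param shell Basis shell per atom.
#' @return A `data.frame` with columns `R`, `branch`, one column per ansatz
#'   parameter, `energy`, `value`, `hessian_index`, `label`.
#' @export
solution_curves <- function(embedding, R_values,
                            objective = c("energy", "variance",
                                          "local_square_gradient"),
                            grid_density = 720, shell = sto3g_hydrogen()) {
  objective <- match.arg(objective)
  if (any(R_values < 0.8 | R_values > 10)) {
    stop("`R_values` must lie within [0.8, 10] bohr", call. = FALSE)
  }
  R_values <- sort(R_values)
  pn <- embedding$parameter_names
  rows <- list()
  prev <- NULL
  next_branch <- 1L
  for (R in R_values) {
    H <- build_csf_hamiltonian(R, shell)$matrix
    sps <- find_stationary_points(embedding, H, objective, grid_density)
    branch_ids <- integer(length(sps))
    if (is.null(prev)) {
      branch_ids <- seq_along(sps)
      next_branch <- length(sps) + 1L
    } else {
      taken <- rep(FALSE, length(prev$points))
      for (i in seq_along(sps)) {
        d <- vapply(seq_along(prev$points), function(j) {
          v <- sps[[i]]$point; w <- prev$points[[j]]
          min(sqrt(sum((v - w)^2)), sqrt(sum((v + w)^2)))
        }, 0)
        d[taken] <- Inf
        j <- which.min(d)
        if (length(j) == 1 && is.finite(d[j]) && d[j] < 0.5) {
          branch_ids[i] <- prev$branches[j]
          taken[j] <- TRUE
        } else {
          branch_ids[i] <- next_branch
          next_branch <- next_branch + 1L
          message("branch birth at R = ", R, " (branch ", branch_ids[i], ")")
        }
      }
      lost <- prev$branches[!taken]
      for (b in lost) message("branch death after R = ", prev$R, " (branch ", b, ")")
    }
    for (i in seq_along(sps)) {
      rec <- sps[[i]]
      row <- c(list(R = R, branch = branch_ids[i]),
               as.list(rec$parameters),
               list(energy = rec$energy, value = rec$value,
                    hessian_index = rec$hessian_index, label = rec$label))
      rows[[length(rows) + 1L]] <- row
    }
    prev <- list(points = lapply(sps, `[[`, "point"), branches = branch_ids, R = R)
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
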