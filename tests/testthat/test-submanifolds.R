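test_that("RHF embedding produces the expected CSF vectors", {
  emb <- rhf_embedding()
  expect_equal(emb$map(0), c(1, 0, 0))
  expect_equal(emb$map(pi / 2), c(0, 0, 1), tolerance = 1e-15)
  set.seed(3)
  for (phi in runif(20, -pi, pi)) {
    v <- emb$map(phi)
    expect_equal(sum(v^2), 1, tolerance = 1e-14)
  }
})

test_that("ESMF embedding reduces to RHF at theta = 0 and reaches the open-shell CSF", {
  emb <- esmf_embedding()
  rhf <- rhf_embedding()
  set.seed(7)
  for (phi in runif(10, 0, pi)) {
    expect_equal(emb$map(c(0, phi)), rhf$map(phi), tolerance = 1e-14)
  }
  expect_equal(emb$map(c(pi / 2, 0)), c(0, 1, 0), tolerance = 1e-14)
  for (i in 1:10) {
    t0 <- c(runif(1, 0, 2 * pi), runif(1, 0, pi))
    expect_equal(sum(emb$map(t0)^2), 1, tolerance = 1e-14)
  }
})

test_that("embedding derivatives match finite differences and stay tangent", {
  set.seed(12)
  for (emb in list(rhf_embedding(), esmf_embedding())) {
    p <- length(emb$parameter_names)
    for (rep in 1:6) {
      t0 <- runif(p, 0, pi)
      J <- emb$jacobian(t0)
      # tangency: c^T dc/dt_a = 0
      expect_equal(drop(crossprod(emb$map(t0), J)), rep(0, p),
                   tolerance = 1e-12)
      fdJ <- t(vapply(1:3, function(i) {
        fd_param_grad(function(t) emb$map(t)[i], t0)
      }, numeric(p)))
      expect_equal(matrix(J, 3, p), matrix(fdJ, 3, p), tolerance = 1e-7)
      D2 <- emb$second_derivatives(t0)
      for (i in 1:3) {
        fdH <- fd_param_hess(function(t) emb$map(t)[i], t0)
        expect_equal(matrix(D2[i, , ], p, p), fdH, tolerance = 1e-5)
      }
    }
  }
})

test_that("constrained gradient and Hessian match finite differences", {
  H <- build_csf_hamiltonian(2.5)$matrix
  set.seed(13)
  for (emb in list(rhf_embedding(), esmf_embedding())) {
    p <- length(emb$parameter_names)
    for (obj in c("energy", "variance", "local_square_gradient")) {
      t0 <- runif(p, 0, pi)
      f <- function(t) ansatz_objective(emb, t, H, obj)
      expect_equal(constrained_gradient(emb, t0, H, obj), fd_param_grad(f, t0),
                   tolerance = 1e-6)
      expect_equal(constrained_hessian(emb, t0, H, obj), fd_param_hess(f, t0),
                   tolerance = 1e-4)
    }
  }
})

test_that("energy through the embedding equals the hypersphere energy", {
  H <- build_csf_hamiltonian(1.8)$matrix
  emb <- esmf_embedding()
  set.seed(14)
  for (rep in 1:20) {
    t0 <- c(runif(1, 0, 2 * pi), runif(1, 0, pi))
    expect_equal(ansatz_objective(emb, t0, H, "energy"),
                 state_energy(emb$map(t0), H), tolerance = 1e-12)
  }
})

test_that("symmetry-pure configurations are Brillouin-stationary", {
  H <- build_csf_hamiltonian(2)$matrix
  emb <- rhf_embedding()
  expect_lt(abs(constrained_gradient(emb, 0, H, "energy")), 1e-12)
  expect_lt(abs(constrained_gradient(emb, pi / 2, H, "energy")), 1e-12)
})

test_that("RHF solution count changes from two to four on bond stretching", {
  H_eq <- build_csf_hamiltonian(1.437707)$matrix
  sp_eq <- find_stationary_points(rhf_embedding(), H_eq, "energy")
  expect_length(sp_eq, 2L)
  df_eq <- as.data.frame(sp_eq)
  expect_setequal(df_eq$label, c("minimum", "maximum"))
  # min = sigma_g^2, max = sigma_u^2 (symmetry-pure angles 0 and pi/2)
  expect_equal(sort(df_eq$phi), c(0, pi / 2), tolerance = 1e-8)

  H_s <- build_csf_hamiltonian(3)$matrix
  sp_s <- find_stationary_points(rhf_embedding(), H_s, "energy")
  expect_length(sp_s, 4L)
  df_s <- as.data.frame(sp_s)
  # the symmetry-broken maxima form a degenerate pair
  broken <- df_s[!(abs(df_s$phi) < 1e-8 | abs(df_s$phi - pi / 2) < 1e-8), ]
  expect_identical(nrow(broken), 2L)
  expect_identical(broken$degeneracy_group[1], broken$degeneracy_group[2])
  expect_equal(broken$energy[1], broken$energy[2], tolerance = 1e-10)
  # sigma_u^2 becomes a local minimum of the RHF energy at dissociation
  u_row <- df_s[abs(df_s$phi - pi / 2) < 1e-8, ]
  expect_identical(u_row$label, "minimum")
})

test_that("variance landscape on the RHF circle has sigma-SCF structure at R = 3", {
  H <- build_csf_hamiltonian(3)$matrix
  sp <- find_stationary_points(rhf_embedding(), H, "variance")
  df <- as.data.frame(sp)
  expect_identical(sum(df$label == "minimum"), 3L)
  expect_identical(sum(df$label == "maximum"), 3L)
  # the sigma_u^2 configuration is a variance maximum here
  u_row <- df[abs(df$phi - pi / 2) < 1e-8, ]
  expect_identical(nrow(u_row), 1L)
  expect_identical(u_row$label, "maximum")
  # while remaining a minimum of the RHF energy itself
  spE <- as.data.frame(find_stationary_points(rhf_embedding(), H, "energy"))
  expect_identical(spE$label[abs(spE$phi - pi / 2) < 1e-8], "minimum")
})

test_that("minima and maxima alternate around the periodic RHF circle", {
  for (R in c(1.437707, 2.2, 3, 5)) {
    H <- build_csf_hamiltonian(R)$matrix
    for (obj in c("energy", "variance")) {
      df <- as.data.frame(find_stationary_points(rhf_embedding(), H, obj))
      expect_identical(sum(df$label == "minimum"), sum(df$label == "maximum"))
    }
  }
})

test_that("square-gradient objective separates physical from artifact solutions", {
  H <- build_csf_hamiltonian(3)$matrix
  emb <- rhf_embedding()
  # zero exactly at every energy-stationary angle
  spE <- find_stationary_points(emb, H, "energy")
  for (r in spE) {
    expect_lt(sgm_objective(emb, r$parameters, H), 1e-14)
  }
  # strictly positive at the unphysical variance maxima
  spV <- as.data.frame(find_stationary_points(emb, H, "variance"))
  artifacts <- spV[spV$label == "maximum" & abs(spV$phi - pi / 2) > 1e-6, ]
  expect_identical(nrow(artifacts), 2L)
  for (phi in artifacts$phi) {
    expect_gt(sgm_objective(emb, phi, H), 1e-3)
  }
  # SGM minima coincide with the energy-stationary set
  spS <- as.data.frame(find_stationary_points(emb, H, "local_square_gradient"))
  sgm_min <- sort(spS$phi[spS$label == "minimum" & spS$value < 1e-12])
  expect_equal(sgm_min, sort(as.data.frame(spE)$phi), tolerance = 1e-6)
  # definition check
  set.seed(31)
  t0 <- runif(1, 0, pi)
  g <- constrained_gradient(emb, t0, H, "energy")
  expect_equal(sgm_objective(emb, t0, H), sum(g^2), tolerance = 1e-14)
})

test_that("ESMF landscape at equilibrium: exact global minimum, RHF saddle", {
  H <- build_csf_hamiltonian(1.437707)$matrix
  emb <- esmf_embedding()
  ev <- sort(eigen(H, symmetric = TRUE)$values)

  # the RHF ground state is gradient-stationary on the ESMF surface ...
  g0 <- constrained_gradient(emb, c(0, 0), H, "energy")
  expect_lt(sqrt(sum(g0^2)), 1e-9)
  # ... but is an index-1 saddle of the two-parameter energy
  lam <- eigen(constrained_hessian(emb, c(0, 0), H, "energy"))$values
  expect_identical(sum(lam < -1e-9), 1L)

  sp <- find_stationary_points(emb, H, "energy")
  df <- as.data.frame(sp)
  gm <- df[which.min(df$energy), ]
  expect_identical(gm$label, "minimum")
  expect_equal(gm$energy, ev[1], tolerance = 1e-8)
  expect_equal(abs(gm$theta), 0.5026, tolerance = 5e-5)
  expect_equal(abs(gm$phi), 0.3304, tolerance = 5e-5)
  # theta and phi rotate in opposite senses at the minimum
  expect_lt(gm$theta * gm$phi, 0)
  # the open-shell singlet is reached exactly, as an index-1 saddle
  os <- df[abs(df$energy - ev[2]) < 1e-8, ]
  expect_identical(nrow(os), 1L)
  expect_identical(os$label, "index-1 saddle")
  os_vec <- sp[[which(abs(df$energy - ev[2]) < 1e-8)]]$point
  expect_equal(abs(os_vec), c(0, 1, 0), tolerance = 1e-7)
  # the double excitation stays the closed-shell sigma_u^2 RHF maximum
  expect_equal(abs(sp[[which(df$label == "maximum")]]$point), c(0, 0, 1),
               tolerance = 1e-7)
})

test_that("ESMF global minimum is exact across bond lengths and below RHF", {
  emb <- esmf_embedding()
  rhf <- rhf_embedding()
  for (R in c(1.437707, 3, 6)) {
    H <- build_csf_hamiltonian(R)$matrix
    ev0 <- min(eigen(H, symmetric = TRUE)$values)
    sp <- find_stationary_points(emb, H, "energy", grid_density = 360)
    e_esmf <- min(vapply(sp, `[[`, 0, "energy"))
    expect_equal(e_esmf, ev0, tolerance = 1e-8)
    e_rhf <- min(vapply(find_stationary_points(rhf, H, "energy"), `[[`, 0, "energy"))
    expect_lte(e_esmf, e_rhf + 1e-12)
    if (R == 1.437707) expect_lt(e_esmf, e_rhf - 1e-3)
  }
})

test_that("RHF energy stationary points appear in the theta = 0 slice of ESMF", {
  H <- build_csf_hamiltonian(3)$matrix
  rhf_phis <- sort(as.data.frame(find_stationary_points(rhf_embedding(), H, "energy"))$phi)
  emb <- esmf_embedding()
  for (phi in rhf_phis) {
    g <- constrained_gradient(emb, c(0, phi), H, "energy")
    # the phi-component must vanish; the theta direction may be downhill
    expect_lt(abs(g[2]), 1e-8)
  }
})

test_that("solution curves track branch births across the Coulson-Fischer point", {
  Rs <- c(1.437707, 2, 2.5, 3)
  suppressMessages({
    tab <- solution_curves(rhf_embedding(), Rs, "energy", grid_density = 360)
  })
  counts <- table(tab$R)
  expect_identical(as.integer(counts[as.character(c(1.437707, 2))]), c(2L, 2L))
  expect_identical(as.integer(counts[as.character(c(2.5, 3))]), c(4L, 4L))
  # branches persist with consistent labels
  expect_true(all(tab$branch[tab$R == 1.437707] %in% tab$branch[tab$R == 3]))
  # sigma-SCF sigma_u^2-like branch exists at all sampled R
  suppressMessages({
    tabv <- solution_curves(rhf_embedding(), Rs, "variance", grid_density = 360)
  })
  for (R in Rs) {
    expect_true(any(abs(tabv$phi[tabv$R == R] - pi / 2) < 1e-6))
  }
})
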