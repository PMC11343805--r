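params <- material_params()

test_that("remodeling tensor is isochoric with the right spectral action", {
  expect_equal(remodeling_tensor(1, c(1, 0, 0)), diag(3))
  expect_equal(det(remodeling_tensor(1.44, c(0, 0, 1))), 1,
               tolerance = 1e-12)
  Fr <- remodeling_tensor(2, c(1, 0, 0))
  expect_equal(as.numeric(Fr %*% c(1, 0, 0)), c(2, 0, 0))
  expect_equal(as.numeric(Fr %*% c(0, 1, 0)), c(0, 2^(-1 / 2), 0))

  set.seed(2)
  for (k in 1:1000) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    expect_lt(abs(det(remodeling_tensor(runif(1, 0.5, 2), a)) - 1), 1e-12)
  }
  expect_error(remodeling_tensor(-0.1, c(1, 0, 0)), "positive")
})

test_that("elastic measures split total stretch by the remodeling stretch", {
  fib <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 1, 0) / sqrt(2),
               c(1, -1, 0) / sqrt(2))
  em <- elastic_measures(diag(3), rep(1, 4), fib)
  expect_equal(em$I4e, rep(1, 4))
  expect_equal(em$I1bar, 3)

  # uniaxial stretch along a fiber: lambda_e = lambda / lambda_r
  a <- c(0, 1, 0)
  lam <- 1.3; lr <- 1.12
  F <- diag(3) + (lam - 1) * a %o% a
  em <- elastic_measures(F, c(lr, 1, 1, 1), fib)
  expect_equal(em$lambda_e[1], lam / lr, tolerance = 1e-12)

  # rigid rotation leaves all elastic measures at their reference values
  th <- 0.7
  Q <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  em <- elastic_measures(Q, rep(1, 4), fib)
  expect_equal(em$I4e, rep(1, 4), tolerance = 1e-12)
  expect_equal(em$I1bar, 3, tolerance = 1e-12)
  expect_error(elastic_measures(-diag(3), rep(1, 4), fib), "inverted")
})

test_that("energy vanishes at the reference state and under fiber compression", {
  fib <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 1, 0) / sqrt(2),
               c(1, -1, 0) / sqrt(2))
  st <- gauss_point_state(params)
  expect_equal(energy_density(diag(3), st, fib, 1, 0, params), 0)

  # compressed fibers (I4e < 1) store no fiber energy: k1 has no effect
  F <- diag(c(0.9, 0.9, 0.9))
  e1 <- energy_density(F, st, fib, 1, 0, params)
  e2 <- energy_density(F, st, fib, 1, 0, material_params(k1 = 1e4))
  expect_equal(e1, e2)

  # volumetric term: rho0 = 1.2 rho0(0), theta = 1, p = 0 -> 0.02 kappa rho0
  rho00 <- initial_density(params)
  st2 <- st
  st2[["C_F"]] <- 0.2 * rho00 / params$alpha  # raise mass by 20 %
  rho0 <- composition(st2, 0, 0, params)$rho0
  expect_equal(rho0 / rho00, 1.2, tolerance = 1e-12)
  ev <- energy_density(diag(3), st2, fib, 1, 0, params)
  expect_equal(ev, rho0 * params$kappa / 2 * 0.2^2, tolerance = 1e-12)
})

test_that("energy is frame-indifferent", {
  set.seed(4)
  fib <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 1, 0) / sqrt(2),
               c(1, -1, 0) / sqrt(2))
  for (k in 1:20) {
    ps <- random_point_state(params)
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    e1 <- energy_density(ps$F, ps$state, ps$fibers, ps$theta, ps$p, params,
                         ps$C_Mo, ps$C_Ma)
    e2 <- energy_density(Q %*% ps$F, ps$state, ps$fibers, ps$theta, ps$p,
                         params, ps$C_Mo, ps$C_Ma)
    expect_lt(abs(e1 - e2) / max(abs(e1), 1), 1e-10)
  }
})

test_that("PK1 matches the finite-difference energy gradient on both Macaulay branches", {
  set.seed(3)
  for (k in 1:30) {
    ps <- random_point_state(params, compressed_fibers = (k %% 2 == 0))
    P <- pk1_and_cauchy_stress(ps$F, ps$state, ps$fibers, ps$theta, ps$p,
                               params, ps$C_Mo, ps$C_Ma)$P
    Pfd <- fd_pk1(ps, params)
    expect_lt(max(abs(P - Pfd)) / max(abs(Pfd)), 1e-6)
  }
  # zero-energy state has zero stress, and the Cauchy stress is symmetric
  st <- gauss_point_state(params)
  fib <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 1, 0) / sqrt(2),
               c(1, -1, 0) / sqrt(2))
  out <- pk1_and_cauchy_stress(diag(3), st, fib, 1, 0, params)
  expect_equal(out$P, matrix(0, 3, 3), tolerance = 1e-14)
  ps <- random_point_state(params)
  sig <- pk1_and_cauchy_stress(ps$F, ps$state, ps$fibers, ps$theta, ps$p,
                               params, ps$C_Mo, ps$C_Ma)$sigma
  expect_equal(sig, t(sig), tolerance = 1e-9 * max(abs(sig)))
})

test_that("deposition prestretch leaves fibers in tension at F = I", {
  fib <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 1, 0) / sqrt(2),
               c(1, -1, 0) / sqrt(2))
  st <- gauss_point_state(params)
  st[3 + 1:4] <- 1 / params$lambda_pre  # remodeled to the homeostatic state
  sig <- pk1_and_cauchy_stress(diag(3), st, fib, 1, 0, params)$sigma
  a <- fib[1, ]
  expect_gt(as.numeric(a %*% sig %*% a), 0)
})

test_that("internal-variable update has the contracted fixed points and cap", {
  fib <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 1, 0) / sqrt(2),
               c(1, -1, 0) / sqrt(2))
  st <- gauss_point_state(params)

  expect_equal(update_internal_variables(st, diag(3), 0, 0, fib, params), st)

  # homeostatic fixed point: lambda_e = lambda_pre -> lambda_r unchanged
  lr0 <- 0.95
  lam_tot <- params$lambda_pre * lr0
  F <- diag(3); F[2, 2] <- lam_tot   # stretch along family 1 = (0,1,0)
  st1 <- st; st1[3 + 1] <- lr0
  up <- update_internal_variables(st1, F, 0, 5 * 86400, fib, params)
  expect_equal(up[["lambda_r1"]], lr0, tolerance = 1e-10)

  # collagen cap: at rho0_c = K_c rho0_c(0) production stops
  st2 <- st
  st2[["rho0_c"]] <- params$K_c * params$rho0_c
  st2[["C_SMC"]] <- 5 * params$C_smc0
  up2 <- update_internal_variables(st2, diag(3), 0, 1e5, fib, params)
  expect_equal(up2[["rho0_c"]], params$K_c * params$rho0_c)

  # cap is never exceeded along a trajectory with strong production
  stt <- st
  stt[["C_SMC"]] <- 20 * params$C_smc0
  for (k in 1:200) {
    stt <- update_internal_variables(stt, diag(3), 0, 5e5, fib, params)
    expect_lte(stt[["rho0_c"]], params$K_c * params$rho0_c * (1 + 1e-10))
  }
  expect_equal(stt[["rho0_c"]] / params$rho0_c, params$K_c,
               tolerance = 1e-6)
})

test_that("foam cells telescope exactly under constant macrophage input", {
  fib <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 1, 0) / sqrt(2),
               c(1, -1, 0) / sqrt(2))
  c_ma <- 3e13
  dt <- 2e5
  n <- 40
  st <- gauss_point_state(params)
  for (k in 1:n) st <- update_internal_variables(st, diag(3), c_ma, dt, fib,
                                                 params)
  expect_equal(st[["C_F"]], params$E_MaF * c_ma * n * dt,
               tolerance = 1e-12)
})

test_that("remodeling relaxes monotonically back to homeostasis", {
  fib <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 1, 0) / sqrt(2),
               c(1, -1, 0) / sqrt(2))
  lr_star <- 0.95
  F <- diag(3); F[2, 2] <- params$lambda_pre * lr_star
  st <- gauss_point_state(params)
  st[3 + 1] <- lr_star * 1.05  # perturbed from the fixed point
  gaps <- numeric(15)
  for (k in 1:15) {
    st <- update_internal_variables(st, F, 0, 2 * 86400, fib, params)
    lam_e <- F[2, 2] / st[["lambda_r1"]]
    gaps[k] <- abs(lam_e - params$lambda_pre)
  }
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[15], 1e-6)
})

test_that("composition is linear with constant cell mass", {
  st <- gauss_point_state(params)
  out <- composition(st, 0, 0, params)
  expect_equal(out$rho0,
               params$rho0_m + params$rho0_c + params$alpha * params$C_smc0)

  st2 <- st
  st2[["C_F"]] <- 4e13; st2[["C_SMC"]] <- 6e13
  c1 <- composition(st2, 1e13, 2e13, params)
  st3 <- st2
  st3[["C_F"]] <- 8e13; st3[["C_SMC"]] <- 12e13
  c2 <- composition(st3, 2e13, 4e13, params)
  expect_equal(c2$rho0_cells, 2 * c1$rho0_cells)

  # alpha * total count: 1e-13 kg/cell x 1e14 cells/m^3 = 10 kg/m^3
  st4 <- gauss_point_state(params)
  st4[["C_SMC"]] <- 0
  expect_equal(composition(st4, 5e13, 5e13, params)$rho0_cells, 10)
})
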