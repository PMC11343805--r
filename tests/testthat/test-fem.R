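params <- material_params()

test_that("residual vanishes at an equilibrium reference state", {
  fx <- frozen_box(params)
  sys <- fx$sys
  st <- initialize_state(sys)
  st$p[dof_index(fx$all_nodes, 4)] <- 1
  st$p_n <- st$p
  # switch consumption and remodeling off so the reference state with
  # uniform nutrients is an exact equilibrium
  p0 <- material_params(R_N = 0, k_r = 0)
  sys0 <- fem_system(fx$mesh, box_fibers(fx$mesh), p0)
  asm <- assemble_residual(sys0, st$p, st$p_n, st$h, 86400)
  expect_true(asm$ok)
  expect_lt(max(abs(asm$R)), 1e-12)
})

test_that("1D nutrient slab matches the closed-form parabola at order 2", {
  # moderate dip: R_N L^2 / (8 D_N) = 0.3 in scaled units
  mp <- material_params(R_N = 2.4e-10, D_N_min = 1e-9, D_N_max = 1e-9)
  errs <- vapply(c(4, 8, 16), function(nx) {
    out <- solve_nutrient_slab(nx, mp)
    expect_true(out$sol$converged)
    expect_lte(out$sol$iterations, 2)  # linear problem
    # L2 error at the Gauss points against the exact solution (the
    # discrete solution is nodally exact in 1D, so the quadrature-point
    # error carries the interpolation order)
    gpc <- atherofem:::cpp_gp_interp(out$sys$nodes, out$sys$elems, out$c_n)
    gpx <- atherofem:::cpp_gp_interp(out$sys$nodes, out$sys$elems, out$x)
    err <- gpc[, 2] - slab_exact(gpx[, 2], mp)
    sqrt(sum(gpc[, 1] * err^2))
  }, numeric(1))
  orders <- log2(errs[-3] / errs[-1])
  expect_gt(min(orders), 1.8)
  expect_lt(max(orders), 2.2)
})

test_that("single element under uniform traction stays homogeneous (patch test)", {
  L <- 0.004
  mesh <- build_box_mesh(L, L, L, c(1, 1, 1))
  sys <- fem_system(mesh, box_fibers(mesh), params)
  st <- initialize_state(sys)
  nd <- mesh$nodes
  all_nodes <- seq_len(sys$n_nodes)
  dir_all <- combine_dirichlet(
    dirichlet(dof_index(which(abs(nd[, 1]) < 1e-12), 1), 0),
    dirichlet(dof_index(which(abs(nd[, 2]) < 1e-12), 2), 0),
    dirichlet(dof_index(which(abs(nd[, 3]) < 1e-12), 3), 0),
    dirichlet(dof_index(all_nodes, 4), 1),
    dirichlet(dof_index(all_nodes, 5), 0),
    dirichlet(dof_index(all_nodes, 6), 0)
  )
  st$p[dof_index(all_nodes, 4)] <- 1
  st$p_n <- st$p
  loads <- list(traction = list(facets = mesh$facets$xmax, t = c(500, 0, 0)))
  sol <- newton_solve(sys, st$p, st$p_n, st$h, 1e4, dir_all, loads)
  expect_true(sol$converged)
  rep <- gp_report(sys, list(p = sol$p, h = sol$h, p_elem = sol$p_elem,
                             theta_elem = sol$theta_elem))
  expect_lt(diff(range(rep$J)), 1e-12)  # homogeneous deformation
  # displacement linear in x on the loaded face
  ux <- sol$p[dof_index(all_nodes, 1)]
  xmax <- which(abs(nd[, 1] - L) < 1e-12)
  expect_lt(diff(range(ux[xmax])), 1e-12)
})

test_that("global tangent matches the FD directional derivative with all couplings", {
  set.seed(7)
  geom <- geometry_spec()
  mesh <- build_half_annulus_mesh(geom, c(2, 2, 2))
  sys <- fem_system(mesh, assign_fiber_directions(mesh), params)
  st <- initialize_state(sys)
  nn <- sys$n_nodes
  p <- st$p
  p[dof_index(seq_len(nn), 4)] <- 1 + 0.1 * runif(nn)
  p[dof_index(seq_len(nn), 5)] <- runif(nn)
  p[dof_index(seq_len(nn), 6)] <- runif(nn)
  for (c in 1:3) p[dof_index(seq_len(nn), c)] <- 1e-4 * rnorm(nn)
  loads <- list(
    pressure = list(facets = mesh$facets$lumen, value = 5e3),
    springs = outer_surface_springs(sys, 1e5)
  )
  dt <- 5 * 86400
  asm <- assemble_tangent(sys, p, st$p, st$h, dt, loads)
  expect_true(asm$ok)
  for (k in 1:3) {
    dp <- rnorm(sys$ndof)
    dp <- dp / sqrt(sum(dp^2))
    eps <- 1e-7
    rp <- assemble_residual(sys, p + eps * dp, st$p, st$h, dt, loads)$R
    rm <- assemble_residual(sys, p - eps * dp, st$p, st$h, dt, loads)$R
    fd <- (rp - rm) / (2 * eps)
    kd <- as.numeric(asm$K %*% dp)
    expect_lt(max(abs(kd - fd)) / max(abs(fd)), 1e-5)
  }
})

test_that("pure diffusion yields an SPD tangent on free dofs", {
  mp <- material_params(R_N = 0)
  fx <- frozen_box(mp, res = c(3, 2, 2))
  sys <- fx$sys
  st <- initialize_state(sys)
  st$p[dof_index(fx$all_nodes, 4)] <- 1
  st$p_n <- st$p
  asm <- assemble_tangent(sys, st$p, st$p_n, st$h, 1)
  free <- dof_index(setdiff(fx$all_nodes, c(fx$xmin_nodes, fx$xmax_nodes)), 4)
  Kff <- as.matrix(asm$K[free, free])
  expect_lt(max(abs(Kff - t(Kff))) / max(abs(Kff)), 1e-9)
  expect_gt(min(eigen(0.5 * (Kff + t(Kff)), only.values = TRUE)$values), 0)
})

test_that("Newton converges superlinearly on an inflation problem", {
  geom <- geometry_spec()
  mesh <- build_half_annulus_mesh(geom, c(2, 4, 2))
  sys <- fem_system(mesh, assign_fiber_directions(mesh), params)
  st <- initialize_state(sys)
  nn <- sys$n_nodes
  conc_idx <- c(dof_index(seq_len(nn), 4), dof_index(seq_len(nn), 5),
                dof_index(seq_len(nn), 6))
  conc_val <- c(rep(1, nn), rep(0, 2 * nn))
  st$p[conc_idx] <- conc_val
  st$p_n <- st$p
  dir_all <- combine_dirichlet(
    atherofem:::mechanical_dirichlet(sys, 0),
    dirichlet(conc_idx, conc_val)
  )
  loads <- list(pressure = list(facets = mesh$facets$lumen, value = 6e3),
                springs = outer_surface_springs(sys, 1e6))
  sol <- newton_solve(sys, st$p, st$p_n, st$h, 86400, dir_all, loads,
                      control = newton_control(atol = 1e-10))
  expect_true(sol$converged)
  r <- sol$residual_history
  expect_gte(length(r), 3)
  # superlinear contraction before the residual reaches the floor set by
  # the element-level differencing
  r <- r[r > 1e-9][1:3]
  order <- log(r[3] / r[2]) / log(r[2] / r[1])
  expect_gt(order, 1.5)
  # prescribed Dirichlet values appear exactly
  expect_true(all(sol$p[dir_all$idx] == dir_all$val))
})

test_that("backward Euler is first order on homogeneous monocyte decay", {
  mp <- material_params(R_N = 0)
  fx <- frozen_box(mp, res = c(2, 1, 1))
  sys <- fx$sys
  rate <- mp$E_MoMa + mp$a_Mo
  t_end <- 2 / rate
  run <- function(nsteps) {
    st <- initialize_state(sys)
    st$p[dof_index(fx$all_nodes, 4)] <- 1
    st$p[dof_index(fx$all_nodes, 5)] <- 1
    st$p_n <- st$p
    dir_all <- combine_dirichlet(
      fx$u_frozen,
      dirichlet(dof_index(fx$all_nodes, 4), 1),
      dirichlet(dof_index(fx$all_nodes, 6), 0)
    )
    for (k in seq_len(nsteps)) {
      st <- time_step(sys, st, t_end / nsteps, dir_all)
      expect_true(isTRUE(attr(st, "converged")))
    }
    st$p[dof_index(1, 5)]
  }
  exact <- exp(-rate * t_end)
  e1 <- abs(run(8) - exact)
  e2 <- abs(run(16) - exact)
  expect_gt(e1 / e2, 1.7)
  expect_lt(e1 / e2, 2.3)
})

test_that("a steady state is a fixed point of further stepping", {
  fx <- frozen_box(params, res = c(2, 1, 1))
  sys <- fx$sys
  st <- initialize_state(sys)
  st$p[dof_index(fx$all_nodes, 4)] <- 1
  st$p_n <- st$p
  dir_all <- combine_dirichlet(
    fx$u_frozen,
    dirichlet(dof_index(fx$all_nodes, 4), 1),
    dirichlet(dof_index(fx$all_nodes, 5), 0),
    dirichlet(dof_index(fx$all_nodes, 6), 0)
  )
  mp0 <- material_params(R_N = 0)
  sys0 <- fem_system(fx$mesh, box_fibers(fx$mesh), mp0)
  s1 <- time_step(sys0, st, 86400, dir_all)
  s2 <- time_step(sys0, s1, 86400, dir_all)
  expect_lt(max(abs(s2$p - s1$p)), 1e-12)
})

test_that("species row scaling constants do not affect the converged solution", {
  mp1 <- material_params(R_N = 2.4e-10)
  mp2 <- material_params(R_N = 2.4e-10, k_cm_N = 1e12, k_cm_Mo = 1e12,
                         k_cm_Ma = 1e12)
  out1 <- solve_nutrient_slab(6, mp1)
  out2 <- solve_nutrient_slab(6, mp2)
  expect_lt(max(abs(out1$c_n - out2$c_n)), 1e-10)
})

test_that("volumetric coupling drives J toward the mass ratio as kappa grows", {
  L <- 0.004
  mesh <- build_box_mesh(L, L, L, c(1, 1, 1))
  errs <- vapply(c(5e3, 5e4, 5e5), function(kap) {
    mp <- material_params(kappa = kap)
    sys <- fem_system(mesh, box_fibers(mesh), mp)
    st <- initialize_state(sys)
    all_nodes <- seq_len(sys$n_nodes)
    # raise the Gauss-point mass by 20 % through foam cells
    st$h[, 1] <- 0.2 * sys$rho00 / mp$alpha
    nd <- mesh$nodes
    dir_all <- combine_dirichlet(
      dirichlet(dof_index(which(abs(nd[, 1]) < 1e-12), 1), 0),
      dirichlet(dof_index(which(abs(nd[, 2]) < 1e-12), 2), 0),
      dirichlet(dof_index(which(abs(nd[, 3]) < 1e-12), 3), 0),
      dirichlet(dof_index(all_nodes, 4), 1),
      dirichlet(dof_index(all_nodes, 5), 0),
      dirichlet(dof_index(all_nodes, 6), 0)
    )
    st$p[dof_index(all_nodes, 4)] <- 1
    st$p_n <- st$p
    # homogeneous-expansion initial guess u = (1.2^(1/3) - 1) X
    lam <- 1.2^(1 / 3)
    for (c in 1:3) {
      st$p[dof_index(all_nodes, c)] <- (lam - 1) * nd[, c]
    }
    sol <- newton_solve(sys, st$p, st$p_n, st$h, 1, dir_all,
                        control = newton_control(max_iter = 40))
    expect_true(sol$converged)
    rep <- gp_report(sys, list(p = sol$p, h = sol$h, p_elem = sol$p_elem,
                               theta_elem = sol$theta_elem))
    abs(mean(rep$J) - 1.2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))  # monotone in kappa over 3 decades
  expect_lt(errs[3], 0.01)
})

test_that("assembly is deterministic", {
  fx <- frozen_box(params)
  sys <- fx$sys
  st <- initialize_state(sys)
  st$p[dof_index(fx$all_nodes, 4)] <- 1 + 0.01 * sin(seq_len(fx$nn))
  st$p_n <- st$p
  a1 <- assemble_residual(sys, st$p, st$p_n, st$h, 1e5)
  a2 <- assemble_residual(sys, st$p, st$p_n, st$h, 1e5)
  expect_identical(a1$R, a2$R)
  expect_identical(a1$h_new, a2$h_new)
})
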