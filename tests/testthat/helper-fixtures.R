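# Shared fixtures: small box systems with selectable physics, and a default
# four-family fiber set for box geometries.

box_fibers <- function(mesh) {
  uniform_fiber_field(mesh, rbind(
    c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0) / sqrt(2), c(1, -1, 0) / sqrt(2)
  ))
}

# A box system with all displacements frozen (pure species problems).
frozen_box <- function(params, L = 0.01, res = c(4, 1, 1),
                       ly = 0.002, lz = 0.002) {
  mesh <- build_box_mesh(L, ly, lz, res)
  sys <- fem_system(mesh, box_fibers(mesh), params)
  nn <- sys$n_nodes
  all_nodes <- seq_len(nn)
  list(
    sys = sys, mesh = mesh, nn = nn, L = L,
    u_frozen = combine_dirichlet(
      dirichlet(dof_index(all_nodes, 1), 0),
      dirichlet(dof_index(all_nodes, 2), 0),
      dirichlet(dof_index(all_nodes, 3), 0)
    ),
    all_nodes = all_nodes,
    xmin_nodes = which(abs(mesh$nodes[, 1]) < 1e-12),
    xmax_nodes = which(abs(mesh$nodes[, 1] - L) < 1e-12)
  )
}

# Solve the steady 1D nutrient slab with Dirichlet value cb at both x-faces;
# returns nodal scaled concentration and the mesh.
solve_nutrient_slab <- function(res_x, params, cb = 1, L = 0.01) {
  fx <- frozen_box(params, L = L, res = c(res_x, 1, 1))
  sys <- fx$sys
  dir_all <- combine_dirichlet(
    fx$u_frozen,
    dirichlet(dof_index(fx$all_nodes, 5), 0),
    dirichlet(dof_index(fx$all_nodes, 6), 0),
    dirichlet(dof_index(c(fx$xmin_nodes, fx$xmax_nodes), 4), cb)
  )
  st <- initialize_state(sys)
  st$p[dof_index(fx$all_nodes, 4)] <- cb
  st$p_n <- st$p
  sol <- newton_solve(sys, st$p, st$p_n, st$h, 1, dir_all)
  list(sys = sys, sol = sol, x = fx$mesh$nodes[, 1],
       c_n = sol$p[dof_index(fx$all_nodes, 4)])
}

slab_exact <- function(x, params, cb = 1, L = 0.01) {
  rn_hat <- params$R_N / params$scale_N
  cb + rn_hat / (2 * params$D_N_max) * x * (x - L)
}

# Random valid Gauss-point inputs for constitutive point tests.
random_point_state <- function(params, compressed_fibers = FALSE) {
  F <- diag(3) + matrix(stats::rnorm(9, 0, 0.06), 3)
  if (det(F) <= 0.2) F <- diag(3)
  lr <- stats::runif(params$n_F, 0.9, 1.1)
  if (compressed_fibers) lr <- lr + 0.5  # pushes I4e below 1
  st <- gauss_point_state(params)
  st[["C_F"]] <- stats::runif(1, 0, 3e13)
  st[["C_SMC"]] <- params$C_smc0 * stats::runif(1, 1, 2)
  st[["rho0_c"]] <- params$rho0_c * stats::runif(1, 1, 3)
  st[3 + seq_len(params$n_F)] <- lr
  fib <- matrix(stats::rnorm(3 * params$n_F), params$n_F)
  fib <- fib / sqrt(rowSums(fib^2))
  list(F = F, state = st, fibers = fib,
       theta = stats::runif(1, 0.9, 1.2), p = stats::rnorm(1, 0, 3e4),
       C_Mo = stats::runif(1, 0, 2e13), C_Ma = stats::runif(1, 0, 2e13))
}

# Central finite difference of the energy density with respect to F.
fd_pk1 <- function(ps, params, h = 1e-6) {
  out <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- ps$F; Fp[i, j] <- Fp[i, j] + h
      Fm <- ps$F; Fm[i, j] <- Fm[i, j] - h
      out[i, j] <- (energy_density(Fp, ps$state, ps$fibers, ps$theta, ps$p,
                                   params, ps$C_Mo, ps$C_Ma) -
                      energy_density(Fm, ps$state, ps$fibers, ps$theta, ps$p,
                                     params, ps$C_Mo, ps$C_Ma)) / (2 * h)
    }
  }
  out
}
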