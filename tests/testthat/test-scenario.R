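test_that("summary quantities are exact on trivial states", {
  cfg <- simulation_config(resolution = c(2, 4, 4))
  mesh <- build_half_annulus_mesh(cfg$geometry, c(2, 4, 4))
  sys <- fem_system(mesh, assign_fiber_directions(mesh), cfg$material)
  st <- initialize_state(sys)
  st$p[dof_index(seq_len(sys$n_nodes), 4)] <- 1
  row <- summarize_states(sys, list(st), cfg)
  # undeformed lumen radius is exactly r_i
  expect_equal(row$lumen_radius_mid, cfg$geometry$r_i)
  expect_equal(row$min_C_N, 1)
  expect_equal(row$int_C_Mo, 0)

  # a uniform unit scaled field integrates to the reference tissue volume
  vol <- integrate_gp_field(sys, rep(1, 8 * sys$n_elems))
  exact_vol <- pi / 2 * (cfg$geometry$r_o^2 - cfg$geometry$r_i^2) *
    cfg$geometry$length
  expect_equal(vol, exact_vol, tolerance = 0.02)  # geometric discretization
  expect_equal(integrate_nodal_field(sys, rep(2, sys$n_nodes)), 2 * vol,
               tolerance = 1e-12)
})

test_that("the monocyte patch sits in the mid-media band", {
  cfg <- simulation_config()
  mesh <- build_half_annulus_mesh(cfg$geometry, cfg$resolution)
  patch <- monocyte_patch_nodes(mesh, cfg)
  expect_gt(length(patch), 0)
  zz <- mesh$nodes[patch, 3]
  rr <- sqrt(mesh$nodes[patch, 1]^2 + mesh$nodes[patch, 2]^2)
  l <- cfg$geometry$length
  expect_true(all(zz >= 0.4 * l - 1e-9 & zz <= 0.6 * l + 1e-9))
  r_lim <- cfg$geometry$r_i + cfg$patch_radial_frac * cfg$geometry$t_im
  expect_true(all(rr <= r_lim + 1e-9))
  # strictly inside the intima-media layer
  expect_true(all(rr <= cfg$geometry$r_i + cfg$geometry$t_im + 1e-9))
})

test_that("config validation guards the degenerate parameter limits", {
  expect_error(material_params(lambda_pre = 1.0), "lambda_pre")
  expect_error(material_params(K_c = 0.5), "K_c")
  expect_error(material_params(rho_tilde = 0.9), "rho_tilde")
  expect_error(simulation_config(disease = list(duration_days = 100,
                                                output_days = c(50, 200))),
               "within the disease duration")
})
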