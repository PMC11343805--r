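params <- material_params()

test_that("plaque size function is a clamped Macaulay ramp", {
  expect_equal(plaque_size_function(1, 1.5), 1)
  expect_equal(plaque_size_function(1.5, 1.5), 0)
  expect_equal(plaque_size_function(2.0, 1.5), 0)   # Macaulay clips
  expect_equal(plaque_size_function(0.8, 1.5), 1)   # upper clamp
  expect_equal(plaque_size_function(1.25, 1.5), 0.5)
  r <- seq(-5, 5, by = 0.01)
  f <- plaque_size_function(r, 1.5)
  expect_true(all(f >= 0 & f <= 1))
  expect_error(plaque_size_function(1, 1), "exceed 1")
})

test_that("nutrient diffusivity interpolates linearly between its bounds", {
  expect_equal(nutrient_diffusivity(1, 1e-10, 1e-9), 1e-9)  # healthy: max
  expect_equal(nutrient_diffusivity(0, 1e-10, 1e-9), 1e-10)
  expect_equal(nutrient_diffusivity(0.5, 1e-10, 1e-9), 5.5e-10)
  f <- runif(50)
  d <- nutrient_diffusivity(f, 1e-10, 1e-9)
  expect_true(all(d >= 1e-10 & d <= 1e-9))
})

test_that("referential fluxes reduce to Fick form at F = I and pull back correctly", {
  g <- c(100, -30, 20)
  out <- nutrient_flux_reaction(g, diag(3), 1e-9, 2e-10)
  expect_equal(out$flux, 1e-9 * g)
  expect_equal(out$reaction, 2e-10)
  expect_equal(nutrient_flux_reaction(c(0, 0, 0), diag(3), 1e-9, 2e-10)$flux,
               c(0, 0, 0))

  # independent Piola pull-back oracle: A = J F^-1 q_spatial with
  # q_spatial = D (F^-T grad_X C)
  set.seed(6)
  F <- diag(c(1.2, 1 / sqrt(1.2), 1 / sqrt(1.2)))  # isochoric stretch
  q_spatial <- 1e-9 * (solve(t(F)) %*% g)
  A_oracle <- det(F) * solve(F) %*% q_spatial
  expect_equal(nutrient_flux_reaction(g, F, 1e-9, 0)$flux,
               as.numeric(A_oracle), tolerance = 1e-12)
})

test_that("monocyte law: chemotaxis toward nutrients, BE decay positivity", {
  gN <- c(50, 0, 0)  # nutrient gradient along +x
  out <- monocyte_flux_reaction(2e13, c(0, 0, 0), gN, 0, diag(3), params)
  expect_gt(out$advective_flux[1], 0)  # physical drift toward nutrients

  p0 <- material_params(r_Mo = 0, D_Mo = 0)
  out0 <- monocyte_flux_reaction(2e13, c(10, 5, 2), gN, 0, diag(3), p0)
  expect_equal(out0$flux, c(0, 0, 0))

  # homogeneous decay under backward Euler is positive and monotone for any dt
  rate <- params$E_MoMa + params$a_Mo
  for (dt in 10^(2:9)) {
    f <- 1 / (1 + dt * rate)
    expect_gt(f, 0); expect_lt(f, 1)
  }
})

test_that("macrophage reaction balances differentiation and transformation", {
  out <- macrophage_flux_reaction(1e13, c(0, 0, 0), c(0, 0, 0), 0, 2e13,
                                  diag(3), params)
  expect_equal(out$reaction,
               -params$E_MoMa * 2e13 + params$E_MaF * 1e13)
  z <- macrophage_flux_reaction(0, c(0, 0, 0), c(0, 0, 0), 0, 0, diag(3),
                                params)
  expect_equal(z$flux, c(0, 0, 0))
  expect_equal(z$reaction, 0)

  # the three reaction terms telescope: d/dt (Mo + Ma + F) = -a_Mo Mo
  c_mo <- 3e13; c_ma <- 2e13
  r_mo <- monocyte_flux_reaction(c_mo, 0 * 1:3, 0 * 1:3, 0, diag(3),
                                 params)$reaction
  r_ma <- macrophage_flux_reaction(c_ma, 0 * 1:3, 0 * 1:3, 0, c_mo, diag(3),
                                   params)$reaction
  r_f <- -params$E_MaF * c_ma  # foam gain enters with opposite sign
  expect_equal(-(r_mo + r_ma + r_f), -params$a_Mo * c_mo)
})

test_that("concentration scaling is the documented bijection", {
  sc <- scale_concentrations(list(C_N = 1e-5, C_Ma = 2e13), params)
  expect_equal(sc$C_N, 1)
  expect_equal(sc$C_Ma, 2)
  x <- list(C_N = 3.2e-6, C_Mo = 7.7e12, C_F = 4e13, C_SMC = 9e12)
  back <- unscale_concentrations(scale_concentrations(x, params), params)
  for (nm in names(x)) {
    expect_equal(back[[nm]], x[[nm]], tolerance = 1e-14)
  }
})
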