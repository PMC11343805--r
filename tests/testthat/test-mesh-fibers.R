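test_that("half-annulus mesh has the expected counts, layers and facets", {
  geom <- geometry_spec(25, 10, 5, 200)
  expect_equal(geom$r_o, 0.040)

  mesh <- build_half_annulus_mesh(geom, c(3, 8, 16))
  expect_equal(nrow(mesh$elems), 3 * 8 * 16)
  expect_equal(nrow(mesh$facets$lumen), 8 * 16)
  expect_gt(min_jacobian(mesh), 0)

  # explicit 1 + 1 radial split: element counts per layer by centroid radius
  m2 <- build_half_annulus_mesh(geom, c(2, 4, 4), n_radial_im = 1)
  expect_equal(as.vector(table(m2$layer)), c(16, 16))
  expect_gt(min_jacobian(m2), 0)

  # outer-node multiplicities are 1 (corners), 2 (edges), 4 (interior)
  expect_setequal(unique(as.integer(mesh$outer_multiplicity)), c(1, 2, 4))

  expect_error(build_half_annulus_mesh(geom, c(1, 4, 4)), "at least 2")
})

test_that("lumen facet area converges to the cylinder surface", {
  geom <- geometry_spec()
  exact <- pi * geom$r_i * geom$length
  err <- vapply(list(c(2, 4, 8), c(2, 8, 16), c(2, 16, 32)), function(r) {
    abs(facet_area(build_half_annulus_mesh(geom, r), "lumen") - exact)
  }, numeric(1))
  expect_true(all(diff(err) < 0))          # decreasing with refinement
  expect_lt(err[3] / exact, 0.005)         # within discretization error
})

test_that("fiber orientation follows elevation and azimuth", {
  # circumferential family at azimuth 0 and pi/2
  expect_equal(fiber_at_point(0.03, 0, 0, 0), c(0, 1, 0))
  expect_equal(fiber_at_point(0, 0.03, 0, 0), c(-1, 0, 0),
               tolerance = 1e-12)
  # axial family independent of position
  expect_equal(fiber_at_point(0.01, 0.02, 0, pi / 2)[3], 1)
  expect_equal(sqrt(sum(fiber_at_point(0.01, 0.02, 5, pi / 5)^2)), 1)
  expect_error(fiber_at_point(0, 0, 0, 0), "axis")
})

test_that("fiber fields are unit norm and rotation-equivariant", {
  geom <- geometry_spec()
  mesh <- build_half_annulus_mesh(geom, c(2, 6, 4))
  fib <- assign_fiber_directions(mesh)
  nf <- attr(fib, "n_F")
  for (j in seq_len(nf)) {
    nrm <- sqrt(rowSums(fib[, 3 * j - 2:0]^2))
    expect_lt(max(abs(nrm - 1)), 1e-12)
  }

  # rotating a point about z rotates the fiber vector identically
  set.seed(1)
  for (k in 1:100) {
    r <- runif(1, 0.025, 0.04)
    th <- runif(1, 0, pi)
    dphi <- runif(1, -1, 1)
    el <- runif(1, -pi / 3, pi / 3)
    a1 <- fiber_at_point(r * cos(th), r * sin(th), 0, el)
    a2 <- fiber_at_point(r * cos(th + dphi), r * sin(th + dphi), 0, el)
    rot <- matrix(c(cos(dphi), sin(dphi), 0,
                    -sin(dphi), cos(dphi), 0,
                    0, 0, 1), 3, 3)
    expect_lt(max(abs(rot %*% a1 - a2)), 1e-10)
  }
})
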