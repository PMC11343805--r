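test_that("a two-level tree is a full binary tree of 7 segments", {
  geom <- geometry_spec()
  # short root far from the clip radius: no truncation can occur
  p <- vv_params(levels = 2L, root_length = 2e-4, seed = 5)
  set.seed(5)
  tr <- generate_tree(c(geom$r_o, 0, 0.1), p, geom)
  expect_equal(nrow(tr), 7)
  expect_equal(sum(tr$level == 0), 1)
  expect_equal(sum(tr$level == 1), 2)
  expect_equal(sum(tr$level == 2), 4)
  # every non-root branch spawns from its parent's endpoint
  ch <- which(!is.na(tr$parent))
  expect_equal(cbind(tr$x1, tr$y1)[ch, ],
               cbind(tr$x2, tr$y2)[tr$parent[ch], ])
})

test_that("generator respects ratio, angle and level ranges over 1e4 branches", {
  geom <- geometry_spec()
  p <- vv_params(root_length = 1e-3, seed = 11)
  set.seed(11)
  trees <- lapply(1:1200, function(i) {
    th <- runif(1, 0, pi)
    generate_tree(c(geom$r_o * cos(th), geom$r_o * sin(th), runif(1, 0, 0.2)),
                  p, geom)
  })
  st <- network_branch_stats(trees)
  expect_gt(length(st$ratios), 1e4)
  expect_true(all(st$ratios > 0.9 & st$ratios < 1.1))
  expect_true(all(st$angles > 2 * pi / 5 & st$angles < 8 * pi / 5))
  expect_true(all(st$levels %in% c(2, 3)))
})

test_that("tree vertices stay in the allowed radial band and axial plane", {
  geom <- geometry_spec()
  p <- vv_params(root_length = 1.9e-3, clip_inner_frac = 0.5, seed = 3)
  set.seed(3)
  r_min <- geom$r_i + 0.5 * geom$t_im
  for (i in 1:50) {
    th <- runif(1, 0, pi)
    z <- runif(1, 0, 0.2)
    tr <- generate_tree(c(geom$r_o * cos(th), geom$r_o * sin(th), z), p, geom)
    expect_true(all(tr$z == z))
    rr <- sqrt(c(tr$x1, tr$x2)^2 + c(tr$y1, tr$y2)^2)
    expect_true(all(rr >= r_min - 1e-9 & rr <= geom$r_o + 1e-9))
  }
})

test_that("network generation is seeded, occlusion-aware and Poisson-sized", {
  geom <- geometry_spec()
  mesh <- build_half_annulus_mesh(geom, c(3, 8, 16))
  p <- vv_params(occlusion_zone = c(0.08, 0.12), seed = 42)
  net1 <- generate_network(mesh, p)
  net2 <- generate_network(mesh, p)
  expect_identical(net1$trees, net2$trees)
  expect_identical(net1$supplied_elements, net2$supplied_elements)

  roots_z <- vapply(net1$trees, function(tr) tr$z[1], numeric(1))
  expect_false(any(roots_z >= 0.08 & roots_z <= 0.12))

  # with no occlusion, mean count over 50 seeds ~ density * length
  lam <- 100 * geom$length
  counts <- vapply(1:50, function(s) {
    length(generate_network(
      mesh, vv_params(trees_per_length = 100, seed = s))$trees)
  }, numeric(1))
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / 50))

  expect_error(generate_network(mesh, vv_params(root_length = 1)), "half")
  expect_warning(
    generate_network(mesh, vv_params(occlusion_zone = c(0, geom$length))),
    "whole axis")
})

test_that("supplied-element marking is geometric and refinement-consistent", {
  geom <- geometry_spec()
  mesh <- build_half_annulus_mesh(geom, c(3, 8, 16))
  expect_identical(mark_supplied_elements(mesh, list()), integer(0))

  # a hand-built radial segment crossing the layer interface marks both
  # elements containing its endpoints
  seg <- data.frame(x1 = 0.039, y1 = 0, x2 = 0.033, y2 = 0, z = 0.05,
                    level = 0, parent = NA, length0 = 6e-3, length = 6e-3,
                    ratio = NA, angle = NA)
  ids <- mark_supplied_elements(mesh, list(seg))
  expect_gte(length(ids), 2)
  lay <- mesh$layer[ids]
  expect_true(all(c("intima_media", "adventitia") %in% as.character(lay)))

  # refining the mesh 2x changes the supplied volume by less than one coarse
  # radial element layer
  p <- vv_params(trees_per_length = 300, root_length = 1.5e-3, seed = 9)
  coarse <- generate_network(mesh, p)
  mesh_f <- build_half_annulus_mesh(geom, c(6, 16, 32))
  fine_ids <- mark_supplied_elements(mesh_f, coarse)
  elem_vols <- function(m) {
    gp <- atherofem:::cpp_gp_interp(m$nodes, m$elems,
                                    numeric(nrow(m$nodes)))[, 1]
    colSums(matrix(gp, nrow = 8))
  }
  v_coarse <- sum(elem_vols(mesh)[coarse$supplied_elements])
  v_fine <- sum(elem_vols(mesh_f)[fine_ids])
  layer_vol <- sum(elem_vols(mesh)[mesh$layer == "adventitia"])
  expect_lt(abs(v_fine - v_coarse), layer_vol)
})
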