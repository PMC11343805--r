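#' Geometry of the idealized two-layer half artery
#'
#' Half of a straight cylindrical artery (symmetry plane y = 0, modeled half
#' y >= 0, cylinder axis z) with an inner intima-media layer and an outer
#' adventitia.  Dimensions are entered in millimetres and converted to SI
#' metres once, here; every downstream contract is SI.
#'
#' @param r_i_mm inner (lumen) radius, mm.
#' @param t_im_mm intima-media thickness, mm.
#' @param t_a_mm adventitia thickness, mm.
#' @param length_mm axial length, mm.
#' @return A `geometry_spec` object with fields in metres
#'   (`r_i`, `r_o`, `t_im`, `t_a`, `length`).
#' @export
geometry_spec <- function(r_i_mm = 25, t_im_mm = 10, t_a_mm = 5,
                          length_mm = 200) {
  stopifnot(r_i_mm > 0, t_im_mm > 0, t_a_mm > 0, length_mm > 0)
  g <- list(
    r_i = r_i_mm * 1e-3,
    t_im = t_im_mm * 1e-3,
    t_a = t_a_mm * 1e-3,
    r_o = (r_i_mm + t_im_mm + t_a_mm) * 1e-3,
    length = length_mm * 1e-3
  )
  class(g) <- "geometry_spec"
  g
}

# Orient facet node cycles so (p2-p1) x (p4-p1) points along `outward`
# (a function of the facet centroid returning the desired direction).
orient_facets <- function(nodes, facets, outward) {
  for (f in seq_len(nrow(facets))) {
    idx <- facets[f, ]
    p <- nodes[idx, , drop = FALSE]
    nrm <- c(
      (p[2, 2] - p[1, 2]) * (p[4, 3] - p[1, 3]) -
        (p[2, 3] - p[1, 3]) * (p[4, 2] - p[1, 2]),
      (p[2, 3] - p[1, 3]) * (p[4, 1] - p[1, 1]) -
        (p[2, 1] - p[1, 1]) * (p[4, 3] - p[1, 3]),
      (p[2, 1] - p[1, 1]) * (p[4, 2] - p[1, 2]) -
        (p[2, 2] - p[1, 2]) * (p[4, 1] - p[1, 1])
    )
    if (sum(nrm * outward(colMeans(p))) < 0) {
      facets[f, ] <- idx[c(1, 4, 3, 2)]
    }
  }
  facets
}

structured_hex_connectivity <- function(ni, nj, nk) {
  # node id for grid index (i, j, k), 0-based indices
  nid <- function(i, j, k) 1 + i + (ni + 1) * (j + (nj + 1) * k)
  elems <- matrix(0L, ni * nj * nk, 8)
  e <- 0
  for (k in 0:(nk - 1)) {
    for (j in 0:(nj - 1)) {
      for (i in 0:(ni - 1)) {
        e <- e + 1
        elems[e, ] <- c(
          nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k), nid(i, j + 1, k),
          nid(i, j, k + 1), nid(i + 1, j, k + 1), nid(i + 1, j + 1, k + 1),
          nid(i, j + 1, k + 1)
        )
      }
    }
  }
  list(elems = elems, nid = nid)
}

#' Build the half-annulus hexahedral mesh
#'
#' Structured discretization of the half artery with `res[1]` radial,
#' `res[2]` circumferential and `res[3]` axial elements.  The radial
#' discretization is split between the layers so that an element interface
#' coincides exactly with the intima-media/adventitia boundary; each element
#' is labelled with its layer.  Boundary facet sets (`lumen`, `outer`,
#' `symmetry`, `z0`, `zl`) are populated with outward-oriented quads, and the
#' multiplicity of every outer-surface node (number of adjacent outer facets,
#' 1, 2 or 4) is recorded for the embedding springs.
#'
#' @param geom a [geometry_spec()].
#' @param res integer vector (radial, circumferential, axial), each >= 2
#'   except that a radial count of 2 (one element per layer) is the minimum.
#' @param n_radial_im number of radial elements in the intima-media layer;
#'   default splits `res[1]` proportionally to the layer thicknesses.
#' @return A `mesh` object: `nodes` (n x 3, metres), `elems` (n_el x 8,
#'   VTK hexahedron ordering), `layer` (factor per element), `facets` (list of
#'   oriented quad matrices), `outer_multiplicity` (named per outer node),
#'   `geom`, `res`.
#' @export
build_half_annulus_mesh <- function(geom, res = c(3, 8, 16),
                                    n_radial_im = NULL) {
  stopifnot(inherits(geom, "geometry_spec"), length(res) == 3)
  nr <- as.integer(res[1]); nc <- as.integer(res[2]); nz <- as.integer(res[3])
  if (nr < 2 || nc < 2 || nz < 2) {
    stop("resolution must be at least 2 elements in every direction")
  }
  if (is.null(n_radial_im)) {
    n_radial_im <- round(nr * geom$t_im / (geom$t_im + geom$t_a))
    n_radial_im <- max(1L, min(nr - 1L, as.integer(n_radial_im)))
  }
  n_im <- as.integer(n_radial_im)
  n_a <- nr - n_im
  if (n_im < 1 || n_a < 1) {
    stop("radial resolution cannot conform to the layer interface: need at ",
         "least one element per layer")
  }
  r_break <- geom$r_i + geom$t_im
  rs <- c(seq(geom$r_i, r_break, length.out = n_im + 1),
          seq(r_break, geom$r_o, length.out = n_a + 1)[-1])
  thetas <- seq(0, pi, length.out = nc + 1)
  zs <- seq(0, geom$length, length.out = nz + 1)

  grid <- expand.grid(r = rs, theta = thetas, z = zs)
  nodes <- cbind(
    grid$r * cos(grid$theta),
    grid$r * sin(grid$theta),
    grid$z
  )
  conn <- structured_hex_connectivity(nr, nc, nz)
  elems <- conn$elems
  nid <- conn$nid

  # layer label from the mean nodal radius (robust to chord shrinkage of
  # coarse circumferential discretizations)
  cen_r <- vapply(seq_len(nrow(elems)), function(e) {
    p <- nodes[elems[e, ], , drop = FALSE]
    mean(sqrt(p[, 1]^2 + p[, 2]^2))
  }, numeric(1))
  layer <- factor(ifelse(cen_r < r_break, "intima_media", "adventitia"),
                  levels = c("intima_media", "adventitia"))

  lumen <- do.call(rbind, lapply(0:(nz - 1), function(k) {
    do.call(rbind, lapply(0:(nc - 1), function(j) {
      c(nid(0, j, k), nid(0, j + 1, k), nid(0, j + 1, k + 1), nid(0, j, k + 1))
    }))
  }))
  outer <- do.call(rbind, lapply(0:(nz - 1), function(k) {
    do.call(rbind, lapply(0:(nc - 1), function(j) {
      c(nid(nr, j, k), nid(nr, j + 1, k), nid(nr, j + 1, k + 1),
        nid(nr, j, k + 1))
    }))
  }))
  symf <- do.call(rbind, lapply(0:(nz - 1), function(k) {
    rbind(
      do.call(rbind, lapply(0:(nr - 1), function(i) {
        c(nid(i, 0, k), nid(i + 1, 0, k), nid(i + 1, 0, k + 1), nid(i, 0, k + 1))
      })),
      do.call(rbind, lapply(0:(nr - 1), function(i) {
        c(nid(i, nc, k), nid(i + 1, nc, k), nid(i + 1, nc, k + 1),
          nid(i, nc, k + 1))
      }))
    )
  }))
  z0 <- do.call(rbind, lapply(0:(nc - 1), function(j) {
    do.call(rbind, lapply(0:(nr - 1), function(i) {
      c(nid(i, j, 0), nid(i + 1, j, 0), nid(i + 1, j + 1, 0), nid(i, j + 1, 0))
    }))
  }))
  zl <- do.call(rbind, lapply(0:(nc - 1), function(j) {
    do.call(rbind, lapply(0:(nr - 1), function(i) {
      c(nid(i, j, nz), nid(i + 1, j, nz), nid(i + 1, j + 1, nz),
        nid(i, j + 1, nz))
    }))
  }))

  facets <- list(
    lumen = orient_facets(nodes, lumen, function(ctr) {
      -c(ctr[1], ctr[2], 0) / sqrt(ctr[1]^2 + ctr[2]^2)
    }),
    outer = orient_facets(nodes, outer, function(ctr) {
      c(ctr[1], ctr[2], 0) / sqrt(ctr[1]^2 + ctr[2]^2)
    }),
    symmetry = orient_facets(nodes, symf, function(ctr) c(0, -1, 0)),
    z0 = orient_facets(nodes, z0, function(ctr) c(0, 0, -1)),
    zl = orient_facets(nodes, zl, function(ctr) c(0, 0, 1))
  )

  mult <- table(as.vector(facets$outer))
  outer_multiplicity <- stats::setNames(as.integer(mult), names(mult))

  m <- list(
    nodes = nodes, elems = elems, layer = layer, facets = facets,
    outer_multiplicity = outer_multiplicity, geom = geom,
    res = c(nr, nc, nz), n_radial_im = n_im, r_breaks = rs,
    thetas = thetas, zs = zs
  )
  class(m) <- "mesh"
  m
}

#' Structured box mesh for verification problems
#'
#' A rectangular box `[0, lx] x [0, ly] x [0, lz]` discretized with trilinear
#' hexahedra, used by the manufactured/closed-form verification problems
#' (1D nutrient slab, patch tests, conservation checks).  Facet sets
#' `xmin/xmax/ymin/ymax/zmin/zmax` are oriented outward.
#'
#' @param lx,ly,lz box dimensions, metres.
#' @param res integer vector of element counts (nx, ny, nz).
#' @return a `mesh` object (single layer `intima_media`).
#' @export
build_box_mesh <- function(lx, ly, lz, res = c(4, 1, 1)) {
  nx <- as.integer(res[1]); ny <- as.integer(res[2]); nz <- as.integer(res[3])
  stopifnot(nx >= 1, ny >= 1, nz >= 1, lx > 0, ly > 0, lz > 0)
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  grid <- expand.grid(x = xs, y = ys, z = zs)
  nodes <- cbind(grid$x, grid$y, grid$z)
  conn <- structured_hex_connectivity(nx, ny, nz)
  nid <- conn$nid
  face <- function(fix, dirfun) {
    out <- switch(fix,
      xmin = do.call(rbind, lapply(0:(nz - 1), function(k)
        do.call(rbind, lapply(0:(ny - 1), function(j)
          c(nid(0, j, k), nid(0, j + 1, k), nid(0, j + 1, k + 1),
            nid(0, j, k + 1)))))),
      xmax = do.call(rbind, lapply(0:(nz - 1), function(k)
        do.call(rbind, lapply(0:(ny - 1), function(j)
          c(nid(nx, j, k), nid(nx, j + 1, k), nid(nx, j + 1, k + 1),
            nid(nx, j, k + 1)))))),
      ymin = do.call(rbind, lapply(0:(nz - 1), function(k)
        do.call(rbind, lapply(0:(nx - 1), function(i)
          c(nid(i, 0, k), nid(i + 1, 0, k), nid(i + 1, 0, k + 1),
            nid(i, 0, k + 1)))))),
      ymax = do.call(rbind, lapply(0:(nz - 1), function(k)
        do.call(rbind, lapply(0:(nx - 1), function(i)
          c(nid(i, ny, k), nid(i + 1, ny, k), nid(i + 1, ny, k + 1),
            nid(i, ny, k + 1)))))),
      zmin = do.call(rbind, lapply(0:(ny - 1), function(j)
        do.call(rbind, lapply(0:(nx - 1), function(i)
          c(nid(i, j, 0), nid(i + 1, j, 0), nid(i + 1, j + 1, 0),
            nid(i, j + 1, 0)))))),
      zmax = do.call(rbind, lapply(0:(ny - 1), function(j)
        do.call(rbind, lapply(0:(nx - 1), function(i)
          c(nid(i, j, nz), nid(i + 1, j, nz), nid(i + 1, j + 1, nz),
            nid(i, j + 1, nz))))))
    )
    orient_facets(nodes, out, dirfun)
  }
  facets <- list(
    xmin = face("xmin", function(ctr) c(-1, 0, 0)),
    xmax = face("xmax", function(ctr) c(1, 0, 0)),
    ymin = face("ymin", function(ctr) c(0, -1, 0)),
    ymax = face("ymax", function(ctr) c(0, 1, 0)),
    zmin = face("zmin", function(ctr) c(0, 0, -1)),
    zmax = face("zmax", function(ctr) c(0, 0, 1))
  )
  m <- list(
    nodes = nodes, elems = conn$elems,
    layer = factor(rep("intima_media", nrow(conn$elems)),
                   levels = c("intima_media", "adventitia")),
    facets = facets, outer_multiplicity = integer(0),
    geom = NULL, res = c(nx, ny, nz)
  )
  class(m) <- "mesh"
  m
}

#' Minimum trilinear-map Jacobian over all Gauss points
#' @param mesh a `mesh` object.
#' @return scalar; positive for a valid mesh.
#' @export
min_jacobian <- function(mesh) {
  gp <- cpp_gp_interp(mesh$nodes, mesh$elems, numeric(nrow(mesh$nodes)))
  min(gp[, 1])
}

#' Total facet area of a facet set (bilinear quadrature)
#' @param mesh a `mesh` object.
#' @param set facet set name, e.g. `"lumen"`.
#' @return area in m^2.
#' @export
facet_area <- function(mesh, set) {
  f <- mesh$facets[[set]]
  if (is.null(f)) stop("unknown facet set: ", set)
  g <- 1 / sqrt(3)
  s2 <- matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), ncol = 2, byrow = TRUE)
  tot <- 0
  for (k in seq_len(nrow(f))) {
    p <- mesh$nodes[f[k, ], , drop = FALSE]
    for (q in 1:4) {
      xi <- s2[q, 1] * g; eta <- s2[q, 2] * g
      dxi <- 0.25 * s2[, 1] * (1 + s2[, 2] * eta)
      deta <- 0.25 * (1 + s2[, 1] * xi) * s2[, 2]
      t1 <- colSums(dxi * p)
      t2 <- colSums(deta * p)
      cr <- c(t1[2] * t2[3] - t1[3] * t2[2],
              t1[3] * t2[1] - t1[1] * t2[3],
              t1[1] * t2[2] - t1[2] * t2[1])
      tot <- tot + sqrt(sum(cr^2))
    }
  }
  tot
}

# Shortest element edge over the whole mesh (used by the vasa vasorum
# node-per-element guarantee).
min_element_edge <- function(mesh) {
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                 c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  best <- Inf
  for (e in seq_len(nrow(mesh$elems))) {
    p <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    d <- sqrt(rowSums((p[edges[, 1], ] - p[edges[, 2], ])^2))
    best <- min(best, d)
  }
  best
}

# Locate the structured half-annulus element containing a point (cylindrical
# inversion of the structured grid); returns NA when outside.
locate_element <- function(mesh, pts) {
  if (is.null(mesh$geom)) stop("locate_element requires an annulus mesh")
  nr <- mesh$res[1]; nc <- mesh$res[2]; nz <- mesh$res[3]
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  th <- atan2(pts[, 2], pts[, 1])
  z <- pts[, 3]
  eps <- 1e-12
  i <- findInterval(pmin(pmax(r, mesh$r_breaks[1] + eps),
                         mesh$r_breaks[nr + 1] - eps), mesh$r_breaks,
                    all.inside = TRUE) - 1L
  j <- pmin(pmax(floor(th / pi * nc), 0), nc - 1L)
  k <- pmin(pmax(floor(z / mesh$geom$length * nz), 0), nz - 1L)
  out_of_domain <- r < mesh$r_breaks[1] - 1e-9 |
    r > mesh$r_breaks[nr + 1] + 1e-9 |
    th < -1e-9 | th > pi + 1e-9 | z < -1e-9 | z > mesh$geom$length + 1e-9
  e <- 1L + i + nr * (j + nc * k)
  e[out_of_domain] <- NA_integer_
  e
}
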