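#' Vasa vasorum generator parameters
#'
#' Parameters of the stochastic fractal-tree generator that approximates the
#' vasa vasorum microvessel network on the outer arterial surface.  Each tree
#' lives in a cross-sectional plane (constant z), starts at the adventitial
#' outer surface pointing radially inward, and bifurcates: from the root and
#' from every branch two new branches originate.  Consecutive parent/child
#' lengths are drawn so their ratio lies in `length_ratio_range`, branch
#' rotation angles in `azimuth_range`, and every tree has 2 or 3 bifurcation
#' generations.  An axial occlusion zone contains no trees and models the
#' vasa vasorum obstruction that initiates the disease.
#'
#' @param trees_per_length surface seeding density, trees per metre of axial
#'   length.
#' @param levels permitted bifurcation generation counts (root = generation
#'   0), drawn uniformly per tree.
#' @param length_ratio_range open interval for the parent/child length ratio
#'   `l_i / l_{i+1}`.
#' @param azimuth_range open interval (rad) for the in-plane rotation of a
#'   child direction relative to its parent.
#' @param root_length length of the root segment, m; branch lengths must stay
#'   below half the smallest element edge so every traversed element receives
#'   a tree node.
#' @param occlusion_zone axial interval `c(z_a, z_b)` (m) without trees, or
#'   `NULL`.
#' @param clip_inner_frac trees are clipped where they would penetrate deeper
#'   than `r_i + clip_inner_frac * t_im` (default mid-media).
#' @param seed RNG seed for the network stream.
#' @return a `vv_params` object.
#' @export
vv_params <- function(trees_per_length = 500,
                      levels = c(2L, 3L),
                      length_ratio_range = c(0.9, 1.1),
                      azimuth_range = c(2 * pi / 5, 8 * pi / 5),
                      root_length = 2e-3,
                      occlusion_zone = NULL,
                      clip_inner_frac = 0.5,
                      seed = 1L) {
  stopifnot(
    trees_per_length > 0,
    all(levels >= 1),
    length(length_ratio_range) == 2, all(length_ratio_range > 0),
    diff(length_ratio_range) > 0,
    length(azimuth_range) == 2,
    all(azimuth_range > 0), all(azimuth_range < 2 * pi),
    root_length > 0, clip_inner_frac >= 0, clip_inner_frac <= 1
  )
  if (!is.null(occlusion_zone)) {
    stopifnot(length(occlusion_zone) == 2, diff(occlusion_zone) >= 0)
  }
  p <- list(
    trees_per_length = trees_per_length, levels = as.integer(levels),
    length_ratio_range = length_ratio_range, azimuth_range = azimuth_range,
    root_length = root_length, occlusion_zone = occlusion_zone,
    clip_inner_frac = clip_inner_frac, seed = as.integer(seed)
  )
  class(p) <- "vv_params"
  p
}

#' Generate one fractal vasa vasorum tree
#'
#' Grows a binary fractal tree in the cross-sectional plane of its root.
#' The root segment points radially inward from the outer surface; each
#' branch spawns two children whose lengths satisfy
#' `parent/child in length_ratio_range` and whose directions are the parent
#' direction rotated in-plane by angles drawn from `azimuth_range`.
#' Segments are clipped at the allowed radial band
#' `[r_i + clip_inner_frac * t_im, r_o]`; a clipped branch terminates.
#'
#' Draws from the current RNG stream: seed via `set.seed()` or use
#' [generate_network()] for a managed stream.
#'
#' @param root length-3 point on the outer surface (m).
#' @param params a [vv_params()] object.
#' @param geom a [geometry_spec()] (defines the clip radii).
#' @param min_edge optional smallest mesh element edge (m); when supplied,
#'   `root_length` must be smaller than `min_edge / 2`.
#' @return A `fractal_tree`: data frame of segments with columns
#'   `x1, y1, x2, y2, z, level, parent, length0` (drawn length), `length`
#'   (after clipping), `ratio, angle` (the drawn parent/child ratio and
#'   rotation; `NA` for the root).
#' @export
generate_tree <- function(root, params, geom, min_edge = NULL) {
  if (!is.null(min_edge) && params$root_length >= min_edge / 2) {
    stop("root_length must be below half the smallest element edge so that ",
         "every traversed element contains a tree node")
  }
  r_min <- geom$r_i + params$clip_inner_frac * geom$t_im
  r_max <- geom$r_o
  z <- root[3]
  p0 <- root[1:2]
  dir0 <- -p0 / sqrt(sum(p0^2))  # radially inward
  n_lev <- if (length(params$levels) == 1) params$levels else
    sample(params$levels, 1)

  clip_segment <- function(p, d, len) {
    # largest t in (0, len] keeping |p + t d| within [r_min, r_max]
    tt <- len
    hit <- FALSE
    for (rb in c(r_min, r_max)) {
      # |p + t d|^2 = rb^2  ->  t^2 + 2 t (p.d) + |p|^2 - rb^2 = 0  (|d| = 1)
      b <- sum(p * d)
      cc <- sum(p^2) - rb^2
      disc <- b^2 - cc
      if (disc >= 0) {
        for (t_hit in c(-b - sqrt(disc), -b + sqrt(disc))) {
          if (t_hit > 1e-12 && t_hit < tt) {
            tt <- t_hit
            hit <- TRUE
          }
        }
      }
    }
    list(t = tt, clipped = hit)
  }

  segs <- vector("list", 2^(n_lev + 1) - 1)
  n_seg <- 0
  grow <- function(p, d, len, level, parent, ratio, angle) {
    cl <- clip_segment(p, d, len)
    q <- p + cl$t * d
    n_seg <<- n_seg + 1
    self <- n_seg
    segs[[self]] <<- c(p[1], p[2], q[1], q[2], z, level, parent, len, cl$t,
                       ratio, angle)
    if (cl$clipped || level >= n_lev) return(invisible(NULL))
    for (child in 1:2) {
      rr <- stats::runif(1, params$length_ratio_range[1],
                         params$length_ratio_range[2])
      ang <- stats::runif(1, params$azimuth_range[1], params$azimuth_range[2])
      rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      grow(q, as.vector(rot %*% d), len / rr, level + 1, self, rr, ang)
    }
    invisible(NULL)
  }
  grow(p0, dir0, params$root_length, 0L, NA_integer_, NA_real_, NA_real_)

  out <- as.data.frame(do.call(rbind, segs[seq_len(n_seg)]))
  names(out) <- c("x1", "y1", "x2", "y2", "z", "level", "parent", "length0",
                  "length", "ratio", "angle")
  structure(out, z_tree = z, n_levels = n_lev, class = c("fractal_tree",
                                                         "data.frame"))
}

#' Generate the vasa vasorum network
#'
#' Samples tree roots uniformly over the outer surface of the mesh excluding
#' the axial occlusion zone (the modeled vasa vasorum obstruction), then grows
#' each tree independently with [generate_tree()].  The number of trees is
#' Poisson with mean `trees_per_length * (axial length not occluded)`.
#'
#' @param mesh an annulus `mesh`.
#' @param params a [vv_params()] object; its `seed` drives the stream.
#' @return A `vv_network`: list of `fractal_tree`s plus `params`, `seed` and
#'   the derived `supplied_elements` (see [mark_supplied_elements()]).
#' @export
generate_network <- function(mesh, params) {
  geom <- mesh$geom
  if (is.null(geom)) stop("vasa vasorum networks require an annulus mesh")
  me <- min_element_edge(mesh)
  if (params$root_length >= me / 2) {
    stop("root_length (", params$root_length, " m) must be below half the ",
         "smallest element edge (", signif(me, 3), " m)")
  }
  occ <- params$occlusion_zone
  l_tot <- geom$length
  l_occ <- if (is.null(occ)) 0 else diff(occ)
  l_free <- l_tot - l_occ
  trees <- list()
  if (l_free <= 0) {
    warning("occlusion zone covers the whole axis: empty vasa vasorum network")
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(params$seed)
    n_tree <- stats::rpois(1, params$trees_per_length * l_free)
    if (n_tree > 0) {
      zr <- stats::runif(n_tree)
      z <- if (is.null(occ)) {
        zr * l_tot
      } else {
        # uniform on [0, z_a] U [z_b, l]
        below <- occ[1]
        ifelse(zr * l_free < below, zr * l_free, zr * l_free - below + occ[2])
      }
      th <- stats::runif(n_tree, 0, pi)
      trees <- lapply(seq_len(n_tree), function(i) {
        root <- c(geom$r_o * cos(th[i]), geom$r_o * sin(th[i]), z[i])
        generate_tree(root, params, geom)
      })
    }
  }
  net <- list(trees = trees, params = params, seed = params$seed)
  class(net) <- "vv_network"
  net$supplied_elements <- mark_supplied_elements(mesh, net)
  net
}

#' Elements supplied with nutrients by the vasa vasorum
#'
#' An element is supplied when at least one tree vertex (segment endpoints
#' plus interpolated intra-segment nodes at roughly half-minimum-edge
#' spacing) lies inside it.  Those elements later carry the nutrient
#' Dirichlet condition during the disease phase.
#'
#' @param mesh an annulus `mesh`.
#' @param network a `vv_network` (or bare list of `fractal_tree`s).
#' @return sorted integer vector of element ids (empty for an empty network).
#' @export
mark_supplied_elements <- function(mesh, network) {
  trees <- if (inherits(network, "vv_network")) network$trees else network
  if (length(trees) == 0) return(integer(0))
  ds <- min_element_edge(mesh) / 2
  pts <- do.call(rbind, lapply(trees, function(tr) {
    do.call(rbind, lapply(seq_len(nrow(tr)), function(s) {
      n_sub <- max(1L, ceiling(tr$length[s] / ds))
      tseq <- seq(0, 1, length.out = n_sub + 1)
      cbind(tr$x1[s] + tseq * (tr$x2[s] - tr$x1[s]),
            tr$y1[s] + tseq * (tr$y2[s] - tr$y1[s]),
            tr$z[s])
    }))
  }))
  ids <- locate_element(mesh, pts)
  sort(unique(ids[!is.na(ids)]))
}

#' Branch-level statistics of a network
#'
#' Recomputes every consecutive parent/child length ratio from the stored
#' (drawn) branch lengths, pools the rotation angles and per-tree level
#' counts, e.g. for checking the generator against its configured ranges.
#'
#' @param network a `vv_network` or list of `fractal_tree`s.
#' @return list with vectors `ratios`, `angles`, `levels`.
#' @export
network_branch_stats <- function(network) {
  trees <- if (inherits(network, "vv_network")) network$trees else network
  ratios <- unlist(lapply(trees, function(tr) {
    child <- which(!is.na(tr$parent))
    tr$length0[tr$parent[child]] / tr$length0[child]
  }))
  angles <- unlist(lapply(trees, function(tr) tr$angle[!is.na(tr$angle)]))
  levels <- vapply(trees, function(tr) attr(tr, "n_levels"), numeric(1))
  list(ratios = ratios, angles = angles, levels = levels)
}
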