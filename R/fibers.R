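#' Fiber orientation vector for a cylindrical geometry
#'
#' Unit orientation of a collagen fiber family at a material point of a
#' cylinder aligned with z.  The azimuth follows the point
#' (`theta_az = atan2(y, x)`), the elevation is the material parameter that
#' tilts the family from the circumferential toward the axial direction:
#'
#'   a = (-cos(el) sin(az), cos(el) cos(az), sin(el))
#'
#' @param x,y,z Cartesian position (m); `z` is unused but kept for signature
#'   symmetry.
#' @param elevation elevation angle, rad (0 = circumferential,
#'   pi/2 = axial).
#' @return unit vector of length 3.
#' @export
fiber_at_point <- function(x, y, z = 0, elevation = 0) {
  if (x == 0 && y == 0) {
    stop("fiber orientation undefined on the cylinder axis (x = y = 0)")
  }
  az <- atan2(y, x)
  c(-cos(elevation) * sin(az), cos(elevation) * cos(az), sin(elevation))
}

#' Attach fiber orientations to every Gauss point of a mesh
#'
#' Evaluates the referential unit fiber vectors of `n_F` families at each
#' 2x2x2 Gauss point of every element.  Elevation angles are constant per
#' tissue layer; the default is the four-family architecture: circumferential,
#' axial, and two diagonal families at +/-45 degrees.
#'
#' @param mesh a `mesh` object.
#' @param elevations named list with per-layer elevation angle vectors (rad),
#'   e.g. `list(intima_media = c(0, pi/2, pi/4, -pi/4), adventitia = ...)`.
#'   A plain numeric vector is recycled for both layers.
#' @return A `fiber_field` object: matrix with `8 * n_elements` rows and
#'   `3 * n_F` columns (row = Gauss point, family-major vector components),
#'   with attributes `n_F` and `elevations`.
#' @export
assign_fiber_directions <- function(mesh,
                                    elevations = c(0, pi / 2, pi / 4,
                                                   -pi / 4)) {
  if (!is.list(elevations)) {
    elevations <- list(intima_media = elevations, adventitia = elevations)
  }
  n_f <- length(elevations$intima_media)
  stopifnot(length(elevations$adventitia) == n_f)
  gp_xyz <- gauss_point_positions(mesh)
  if (any(gp_xyz[, 1] == 0 & gp_xyz[, 2] == 0)) {
    stop("Gauss point on the cylinder axis: fiber azimuth undefined")
  }
  az <- atan2(gp_xyz[, 2], gp_xyz[, 1])
  lay <- rep(as.character(mesh$layer), each = 8)
  fib <- matrix(0, nrow(gp_xyz), 3 * n_f)
  for (j in seq_len(n_f)) {
    el <- ifelse(lay == "intima_media",
                 elevations$intima_media[j], elevations$adventitia[j])
    fib[, 3 * j - 2] <- -cos(el) * sin(az)
    fib[, 3 * j - 1] <- cos(el) * cos(az)
    fib[, 3 * j] <- sin(el)
  }
  structure(fib, n_F = n_f, elevations = elevations, class = "fiber_field")
}

#' Uniform fiber field (verification fixtures)
#'
#' Constant referential fiber directions for every Gauss point; used by box
#' fixtures where the cylindrical azimuth is undefined or irrelevant.
#'
#' @param mesh a `mesh` object.
#' @param dirs `n_F x 3` matrix of directions (normalized internally).
#' @return a `fiber_field` object.
#' @export
uniform_fiber_field <- function(mesh, dirs) {
  dirs <- as.matrix(dirs)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  n_f <- nrow(dirs)
  fib <- matrix(rep(as.vector(t(dirs)), each = 8 * nrow(mesh$elems)),
                nrow = 8 * nrow(mesh$elems))
  structure(fib, n_F = n_f, elevations = NULL, class = "fiber_field")
}

# Reference coordinates of all 2x2x2 Gauss points, ordered element-major
# (row = (element - 1) * 8 + gp, matching the C++ kernels).
gauss_point_positions <- function(mesh) {
  g <- 1 / sqrt(3)
  sg <- matrix(c(-1, -1, -1, 1, -1, -1, 1, 1, -1, -1, 1, -1,
                 -1, -1, 1, 1, -1, 1, 1, 1, 1, -1, 1, 1),
               ncol = 3, byrow = TRUE)
  nel <- nrow(mesh$elems)
  out <- matrix(0, nel * 8, 3)
  xs <- matrix(mesh$nodes[t(mesh$elems), 1], nrow = 8)
  ys <- matrix(mesh$nodes[t(mesh$elems), 2], nrow = 8)
  zs <- matrix(mesh$nodes[t(mesh$elems), 3], nrow = 8)
  for (gp in 1:8) {
    xi <- sg[gp, 1] * g; eta <- sg[gp, 2] * g; ze <- sg[gp, 3] * g
    n_w <- 0.125 * (1 + sg[, 1] * xi) * (1 + sg[, 2] * eta) *
      (1 + sg[, 3] * ze)
    rows <- (seq_len(nel) - 1) * 8 + gp
    out[rows, 1] <- colSums(n_w * xs)
    out[rows, 2] <- colSums(n_w * ys)
    out[rows, 3] <- colSums(n_w * zs)
  }
  out
}
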