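# On-disk artifacts: VTU/PVD snapshots, VTP network polylines, YAML
# configuration, JSON metadata.  Everything is plain text; the single
# canonical unit system in files is SI (geometry enters in mm only at config
# ingress).

fmt_num <- function(x) {
  paste(formatC(x, format = "g", digits = 17), collapse = " ")
}

xml_data_array <- function(name, x, type = "Float64", ncomp = 1) {
  sprintf(
    '    <DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n      %s\n    </DataArray>',
    type, name, ncomp, fmt_num(x)
  )
}

#' Write a VTU snapshot of a solver state
#'
#' ASCII XML unstructured-grid file with nodal point data (displacement and
#' scaled concentrations), element cell data (layer, condensed pressure and
#' dilatation) and Gauss-averaged cell data (scaled foam cell and smooth
#' muscle cell concentrations, collagen fold-increase, mass ratio, von Mises
#' Cauchy stress).
#'
#' @param sys a `fem_system`.
#' @param state a `system_state`.
#' @param path output file path (`.vtu`).
#' @param fields point-data fields to include (subset of the default).
#' @param deformed write deformed coordinates `X + u` instead of reference.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(sys, state, path,
                           fields = c("u", "C_N", "C_Mo", "C_Ma"),
                           deformed = FALSE) {
  nn <- sys$n_nodes
  ne <- sys$n_elems
  pr <- state$p
  coords <- sys$nodes
  if (deformed) {
    coords <- coords + cbind(pr[dof_index(seq_len(nn), 1)],
                             pr[dof_index(seq_len(nn), 2)],
                             pr[dof_index(seq_len(nn), 3)])
  }
  pd <- character(0)
  if ("u" %in% fields) {
    u <- cbind(pr[dof_index(seq_len(nn), 1)],
               pr[dof_index(seq_len(nn), 2)],
               pr[dof_index(seq_len(nn), 3)])
    pd <- c(pd, xml_data_array("u", as.vector(t(u)), ncomp = 3))
  }
  conc_map <- c(C_N = 4, C_Mo = 5, C_Ma = 6)
  for (nm in intersect(c("C_N", "C_Mo", "C_Ma"), fields)) {
    pd <- c(pd, xml_data_array(nm, pr[dof_index(seq_len(nn),
                                                conc_map[[nm]])]))
  }
  gp_mean <- function(v) colMeans(matrix(v, nrow = 8))
  rep_df <- gp_report(sys, state)
  cd <- c(
    xml_data_array("layer", as.integer(sys$mesh$layer), type = "Int32"),
    xml_data_array("pressure", state$p_elem),
    xml_data_array("theta", state$theta_elem),
    xml_data_array("C_F", gp_mean(state$h[, 1] / sys$params$scale_cell)),
    xml_data_array("C_SMC", gp_mean(state$h[, 2] / sys$params$scale_cell)),
    xml_data_array("collagen_fold", gp_mean(state$h[, 3] / sys$params$rho0_c)),
    xml_data_array("rho_ratio", gp_mean(rep_df$rho0 / sys$rho00)),
    xml_data_array("von_mises", gp_mean(rep_df$svm))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    " <UnstructuredGrid>",
    sprintf('  <Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne),
    "   <Points>",
    xml_data_array("Points", as.vector(t(coords)), ncomp = 3),
    "   </Points>",
    "   <Cells>",
    xml_data_array("connectivity", as.vector(t(sys$elems)) - 1L,
                   type = "Int32"),
    xml_data_array("offsets", seq_len(ne) * 8L, type = "Int32"),
    xml_data_array("types", rep(12L, ne), type = "UInt8"),
    "   </Cells>",
    "   <PointData>", pd, "   </PointData>",
    "   <CellData>", cd, "   </CellData>",
    "  </Piece>",
    " </UnstructuredGrid>",
    "</VTKFile>"
  ), con)
  invisible(path)
}

#' Read a named point-data array back from a VTU snapshot
#'
#' @param path a `.vtu` file written by [write_snapshot()].
#' @param name point-data array name (e.g. `"C_N"`).
#' @return numeric vector (row-major for multi-component arrays).
#' @export
read_vtu_point_data <- function(path, name) {
  doc <- xml2::read_xml(path)
  arr <- xml2::xml_find_first(doc, sprintf(
    ".//PointData/DataArray[@Name='%s']", name))
  if (inherits(arr, "xml_missing")) stop("no point data array '", name, "'")
  as.numeric(strsplit(trimws(xml2::xml_text(arr)), "\\s+")[[1]])
}

#' Write a PVD index for a snapshot series
#'
#' @param path `.pvd` output path.
#' @param files snapshot file paths.
#' @param times time stamp per file.
#' @return `path`, invisibly.
#' @export
write_pvd <- function(path, files, times) {
  entries <- sprintf(
    '  <DataSet timestep="%s" file="%s"/>',
    formatC(times[seq_along(files)], format = "g"), basename(files)
  )
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="Collection" version="0.1">',
    " <Collection>", entries, " </Collection>", "</VTKFile>"
  ), path)
  invisible(path)
}

#' Export a vasa vasorum network as VTP polylines
#'
#' @param network a `vv_network`.
#' @param path `.vtp` output path.
#' @return `path`, invisibly.
#' @export
write_network_vtp <- function(network, path) {
  segs <- do.call(rbind, lapply(network$trees, function(tr) {
    cbind(tr$x1, tr$y1, tr$z, tr$x2, tr$y2, tr$z, tr$level)
  }))
  if (is.null(segs)) segs <- matrix(0, 0, 7)
  npt <- 2 * nrow(segs)
  pts <- matrix(0, npt, 3)
  if (nrow(segs)) {
    pts[seq(1, npt, 2), ] <- segs[, 1:3]
    pts[seq(2, npt, 2), ] <- segs[, 4:6]
  }
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    " <PolyData>",
    sprintf('  <Piece NumberOfPoints="%d" NumberOfLines="%d">',
            npt, nrow(segs)),
    "   <Points>",
    xml_data_array("Points", as.vector(t(pts)), ncomp = 3),
    "   </Points>",
    "   <Lines>",
    xml_data_array("connectivity", seq_len(npt) - 1L, type = "Int32"),
    xml_data_array("offsets", seq_len(nrow(segs)) * 2L, type = "Int32"),
    "   </Lines>",
    "   <CellData>",
    xml_data_array("level", segs[, 7], type = "Int32"),
    "   </CellData>",
    "  </Piece>",
    " </PolyData>",
    "</VTKFile>"
  ), path)
  invisible(path)
}

# Canonical JSON of a config (functions/classes stripped) for hashing.
config_canonical_json <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, strip)
    } else x
  }
  jsonlite::toJSON(strip(unclass_config(config)), auto_unbox = TRUE,
                   digits = NA, null = "null")
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$geometry <- unclass(out$geometry)
  out$material <- unclass(out$material)
  out$vv <- unclass(out$vv)
  out
}

#' Configuration hash
#'
#' MD5 of the canonical JSON serialization; identical configs hash
#' identically independent of list ordering.
#'
#' @param config a `simulation_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(config_canonical_json(config), tf)
  unname(tools::md5sum(tf))
}

#' Write run metadata
#'
#' @param path `metadata.json` output path.
#' @param config the `simulation_config` of the run.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(path, config) {
  jsonlite::write_json(list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("atherofem")),
    r_version = R.version.string
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Save / load a simulation configuration (YAML)
#'
#' The YAML schema mirrors [simulation_config()]'s arguments (geometry in mm
#' at ingress, everything else SI).  Unknown keys are rejected; values not
#' present in the file keep their package defaults and are tagged
#' `decision-default` in the returned provenance attribute.
#'
#' @param config a `simulation_config`.
#' @param path YAML file path.
#' @return [save_config()]: `path` invisibly; [load_config()]: a validated
#'   `simulation_config` with a `provenance` attribute.
#' @export
save_config <- function(config, path) {
  cfg <- unclass_config(config)
  cfg$band <- NULL  # derived
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c(
    "geometry", "resolution", "material", "vv", "p_blood", "axial_stretch",
    "spring_k", "nutrient_dirichlet_scaled", "monocyte_dirichlet_scaled",
    "band_frac", "patch_radial_frac", "preload", "disease", "seed", "out_dir"
  )
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  check_sub <- function(sub, allowed, label) {
    bad <- setdiff(names(sub), allowed)
    if (length(bad)) {
      stop("unknown ", label, " keys: ", paste(bad, collapse = ", "))
    }
    sub
  }
  geom <- if (is.null(raw$geometry)) geometry_spec() else {
    g <- check_sub(raw$geometry, c("r_i", "t_im", "t_a", "r_o", "length"),
                   "geometry")
    geometry_spec(r_i_mm = g$r_i * 1e3, t_im_mm = g$t_im * 1e3,
                  t_a_mm = g$t_a * 1e3, length_mm = g$length * 1e3)
  }
  mat_args <- check_sub(
    raw$material %||% list(),
    names(formals(material_params)), "material")
  vv_args <- check_sub(raw$vv %||% list(), names(formals(vv_params)), "vv")
  pre <- check_sub(raw$preload %||% list(),
                   c("ramp_steps", "ramp_dt_days", "hold_dt_days",
                     "hold_tol", "max_hold_days"), "preload")
  dis <- check_sub(raw$disease %||% list(),
                   c("duration_days", "output_days", "dt0_days",
                     "dt_max_days", "dt_min_days", "grow"), "disease")
  args <- list(
    geometry = geom,
    material = do.call(material_params, mat_args),
    vv = if (length(vv_args)) do.call(vv_params, vv_args) else NULL,
    preload = pre, disease = dis
  )
  for (k in c("resolution", "p_blood", "axial_stretch", "spring_k",
              "nutrient_dirichlet_scaled", "monocyte_dirichlet_scaled",
              "band_frac", "patch_radial_frac", "seed", "out_dir")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  cfg <- do.call(simulation_config, args)
  prov <- lapply(stats::setNames(nm = known_top), function(k) {
    if (is.null(raw[[k]])) "decision-default" else "config-file"
  })
  attr(cfg, "provenance") <- prov
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a mesh as VTU (with layer cell data and multiplicity point data)
#'
#' Facet sets are serialized to a JSON sidecar (`<path>.facets.json`).
#'
#' @param mesh a `mesh` object.
#' @param path `.vtu` output path.
#' @return `path`, invisibly.
#' @export
write_mesh_vtu <- function(mesh, path) {
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  mult <- numeric(nn)
  if (length(mesh$outer_multiplicity)) {
    mult[as.integer(names(mesh$outer_multiplicity))] <-
      mesh$outer_multiplicity
  }
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    " <UnstructuredGrid>",
    sprintf('  <Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne),
    "   <Points>",
    xml_data_array("Points", as.vector(t(mesh$nodes)), ncomp = 3),
    "   </Points>",
    "   <Cells>",
    xml_data_array("connectivity", as.vector(t(mesh$elems)) - 1L,
                   type = "Int32"),
    xml_data_array("offsets", seq_len(ne) * 8L, type = "Int32"),
    xml_data_array("types", rep(12L, ne), type = "UInt8"),
    "   </Cells>",
    "   <PointData>",
    xml_data_array("multiplicity", mult, type = "Int32"),
    "   </PointData>",
    "   <CellData>",
    xml_data_array("layer", as.integer(mesh$layer), type = "Int32"),
    "   </CellData>",
    "  </Piece>",
    " </UnstructuredGrid>",
    "</VTKFile>"
  ), path)
  jsonlite::write_json(mesh$facets, paste0(path, ".facets.json"))
  invisible(path)
}
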