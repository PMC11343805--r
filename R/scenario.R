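DAY <- 86400  # seconds

#' Simulation configuration
#'
#' Collects geometry, resolution, material and generator parameters, loads,
#' boundary conditions and time-stepping controls for the two-phase
#' experiment: a homeostatic preload under blood pressure, axial stretch and
#' outer embedding springs, followed by the disease phase in which the vasa
#' vasorum occlusion starves a mid-vessel band and monocyte recruitment
#' starts the plaque cascade.
#'
#' @param geometry a [geometry_spec()].
#' @param resolution element counts (radial, circumferential, axial).
#' @param material a [material_params()] object.
#' @param vv a [vv_params()] object; by default its occlusion zone is aligned
#'   with the malnourished band `band_frac`.
#' @param p_blood lumen blood pressure, Pa (follower load).
#' @param axial_stretch prescribed axial end displacement, m.
#' @param spring_k base radial spring stiffness, N/m (scaled 1x/2x/4x by
#'   outer-node multiplicity).
#' @param nutrient_dirichlet_scaled scaled nutrient value at lumen and
#'   vasa-vasorum-supplied elements (1 = 1e-5 kg/m^3).
#' @param monocyte_dirichlet_scaled scaled monocyte recruitment value on the
#'   mid-media patch (10 = 1e14 cells/m^3).
#' @param band_frac axial fraction (centered at l/2) of the occluded /
#'   recruiting band.
#' @param patch_radial_frac radial extent of the monocyte patch as a fraction
#'   of the intima-media thickness measured from the lumen.
#' @param preload list: `ramp_steps`, `ramp_dt_days`, `hold_dt_days`,
#'   `hold_tol` (homeostasis criterion on `|lambda_e - lambda_pre|`),
#'   `max_hold_days`.
#' @param disease list: `duration_days`, `output_days`, `dt0_days`,
#'   `dt_max_days`, `dt_min_days`, `grow` (step-size growth factor after fast
#'   convergence).
#' @param seed RNG seed (vasa vasorum network).
#' @param out_dir output directory for VTU/PVD/CSV artifacts, or `NULL` for
#'   in-memory results only.
#' @return a validated `simulation_config`.
#' @export
simulation_config <- function(geometry = geometry_spec(),
                              resolution = c(3, 8, 16),
                              material = material_params(),
                              vv = NULL,
                              p_blood = 13e3,
                              axial_stretch = 15e-3,
                              spring_k = 8e7,
                              nutrient_dirichlet_scaled = 1,
                              monocyte_dirichlet_scaled = 10,
                              band_frac = 0.2,
                              patch_radial_frac = 2 / 3,
                              preload = list(),
                              disease = list(),
                              seed = 1L,
                              out_dir = NULL) {
  validate_material_params(material)
  preload <- utils::modifyList(list(
    ramp_steps = 6L, ramp_dt_days = 0.25, hold_dt_days = 2,
    hold_tol = 1e-4, max_hold_days = 400
  ), preload)
  disease <- utils::modifyList(list(
    duration_days = 300, output_days = c(30, 180, 300),
    dt0_days = 1, dt_max_days = 6, dt_min_days = 0.01, grow = 1.3
  ), disease)
  if (any(disease$output_days > disease$duration_days)) {
    stop("output times must lie within the disease duration")
  }
  if (band_frac <= 0 || band_frac >= 1) stop("band_frac must be in (0, 1)")
  band <- geometry$length * (0.5 + c(-0.5, 0.5) * band_frac)
  if (is.null(vv)) {
    vv <- vv_params(occlusion_zone = band, seed = seed)
  }
  cfg <- list(
    geometry = geometry, resolution = resolution, material = material,
    vv = vv, p_blood = p_blood, axial_stretch = axial_stretch,
    spring_k = spring_k,
    nutrient_dirichlet_scaled = nutrient_dirichlet_scaled,
    monocyte_dirichlet_scaled = monocyte_dirichlet_scaled,
    band_frac = band_frac, band = band,
    patch_radial_frac = patch_radial_frac,
    preload = preload, disease = disease, seed = as.integer(seed),
    out_dir = out_dir
  )
  class(cfg) <- "simulation_config"
  cfg
}

# Mechanical Dirichlet set: symmetry plane, axial end conditions, rigid-body
# pins at (x = 0, r = r_i) on both end faces.
mechanical_dirichlet <- function(sys, axial_value) {
  nd <- sys$nodes
  geom <- sys$mesh$geom
  sym <- which(abs(nd[, 2]) < 1e-9)
  z0 <- which(abs(nd[, 3]) < 1e-12 + 1e-9)
  zl <- which(abs(nd[, 3] - geom$length) < 1e-12 + 1e-9)
  rr <- sqrt(nd[, 1]^2 + nd[, 2]^2)
  pins <- which(abs(nd[, 1]) < 1e-8 & abs(rr - geom$r_i) < 1e-9 &
                  (abs(nd[, 3]) < 1e-9 |
                     abs(nd[, 3] - geom$length) < 1e-9))
  combine_dirichlet(
    dirichlet(dof_index(sym, 2), 0),
    dirichlet(dof_index(z0, 3), 0),
    dirichlet(dof_index(zl, 3), axial_value),
    dirichlet(dof_index(pins, 1), 0)
  )
}

#' Monocyte recruitment patch
#'
#' Nodes of the mid-media band where nutrient scarcity recruits monocytes:
#' axial band of width `band_frac * l` centered at `l/2`, radially within the
#' inner `patch_radial_frac` of the intima-media layer, full modeled
#' circumference.
#'
#' @param mesh an annulus `mesh`.
#' @param config a `simulation_config`.
#' @return integer node ids.
#' @export
monocyte_patch_nodes <- function(mesh, config) {
  geom <- mesh$geom
  nd <- mesh$nodes
  rr <- sqrt(nd[, 1]^2 + nd[, 2]^2)
  band <- config$band
  r_max <- geom$r_i + config$patch_radial_frac * geom$t_im
  which(nd[, 3] >= band[1] - 1e-9 & nd[, 3] <= band[2] + 1e-9 &
          rr <= r_max + 1e-9)
}

# Nodes carrying the nutrient Dirichlet value during the disease phase:
# lumen surface plus every node of a vasa-vasorum-supplied element.
nutrient_dirichlet_nodes <- function(mesh, supplied_elements) {
  lum <- unique(as.vector(mesh$facets$lumen))
  vvn <- if (length(supplied_elements)) {
    unique(as.vector(mesh$elems[supplied_elements, ]))
  } else integer(0)
  sort(unique(c(lum, vvn)))
}

#' Homeostatic preload phase
#'
#' Builds mesh, fibers and system, ramps blood pressure and axial stretch to
#' their service values and holds them while the collagen remodeling
#' stretches evolve, until every fiber family's elastic stretch matches the
#' deposition prestretch to within `hold_tol` at every Gauss point.  All
#' concentrations are frozen at their initial values (scaled nutrient 1,
#' monocytes and macrophages 0).
#'
#' @param config a [simulation_config()].
#' @param verbose print per-step progress.
#' @return list with the `fem_system`, the homeostatic `system_state`, the
#'   history of the homeostasis gap, and the load/dirichlet builders reused
#'   by the disease phase.
#' @export
run_homeostasis_phase <- function(config, verbose = FALSE) {
  mesh <- build_half_annulus_mesh(config$geometry, config$resolution)
  fibers <- assign_fiber_directions(mesh)
  sys <- fem_system(mesh, fibers, config$material)
  state <- initialize_state(sys)

  conc_idx <- c(dof_index(seq_len(sys$n_nodes), 4),
                dof_index(seq_len(sys$n_nodes), 5),
                dof_index(seq_len(sys$n_nodes), 6))
  conc_val <- c(rep(config$nutrient_dirichlet_scaled, sys$n_nodes),
                rep(0, 2 * sys$n_nodes))
  state$p[conc_idx] <- conc_val
  state$p_n <- state$p

  springs <- outer_surface_springs(sys, config$spring_k)
  gap_hist <- numeric(0)

  run_one <- function(state, frac, dt) {
    dir_all <- combine_dirichlet(
      mechanical_dirichlet(sys, frac * config$axial_stretch),
      dirichlet(conc_idx, conc_val)
    )
    loads <- list(
      pressure = list(facets = sys$mesh$facets$lumen,
                      value = frac * config$p_blood),
      springs = springs
    )
    time_step(sys, state, dt, dir_all, loads,
              control = newton_control(fd_central = FALSE))
  }

  for (s in seq_len(config$preload$ramp_steps)) {
    st <- run_one(state, s / config$preload$ramp_steps,
                  config$preload$ramp_dt_days * DAY)
    if (is.null(attr(st, "converged"))) {
      stop("preload ramp failed at step ", s, ": ", st$reason)
    }
    state <- st
    if (verbose) message("ramp step ", s, " done")
  }

  lam_cols <- function(rep) as.matrix(
    rep[, grep("^lambda_e", names(rep)), drop = FALSE]
  )
  gap <- function(state) {
    max(abs(lam_cols(gp_report(sys, state)) - config$material$lambda_pre))
  }
  g <- gap(state)
  gap_hist <- c(gap_hist, g)
  t_hold <- 0
  dt <- config$preload$hold_dt_days * DAY
  while (g > config$preload$hold_tol) {
    if (t_hold > config$preload$max_hold_days * DAY) {
      stop("homeostasis not reached within ",
           config$preload$max_hold_days, " days; residual gap ", signif(g, 3))
    }
    st <- run_one(state, 1, dt)
    if (is.null(attr(st, "converged"))) {
      dt <- dt / 2
      if (dt < 1) stop("preload hold failed: ", st$reason)
      next
    }
    state <- st
    t_hold <- t_hold + dt
    dt <- min(dt * 2, 20 * DAY)
    g <- gap(state)
    gap_hist <- c(gap_hist, g)
    if (verbose) {
      message("hold t = ", round(t_hold / DAY, 1), " d, gap = ", signif(g, 3))
    }
  }

  list(
    sys = sys, state = state, gap_history = gap_hist,
    springs = springs, conc_idx = conc_idx, conc_val = conc_val,
    config = config
  )
}

# Nodes of intima-media elements whose axial extent overlaps the occluded
# band: the region where the plaque forms.
plaque_region_nodes <- function(sys, config) {
  band_el <- which(sys$mesh$layer == "intima_media" &
                     vapply(seq_len(sys$n_elems), function(e) {
                       zz <- range(sys$nodes[sys$elems[e, ], 3])
                       zz[1] < config$band[2] - 1e-12 &&
                         zz[2] > config$band[1] + 1e-12
                     }, logical(1)))
  sort(unique(as.vector(sys$elems[band_el, ])))
}

# One summary row of a disease-phase state.
summarize_state <- function(sys, state, config, patch_nodes, plaque_nodes,
                            mid_lumen_nodes) {
  pr <- state$p
  sc <- sys$params$scale_cell
  rr_def <- sqrt((sys$nodes[mid_lumen_nodes, 1] +
                    pr[dof_index(mid_lumen_nodes, 1)])^2 +
                   (sys$nodes[mid_lumen_nodes, 2] +
                      pr[dof_index(mid_lumen_nodes, 2)])^2)
  im_gp <- rep(sys$mesh$layer == "intima_media", each = 8)
  cn <- pr[dof_index(seq_len(sys$n_nodes), 4)]
  data.frame(
    t_days = state$t / DAY,
    lumen_radius_mid = min(rr_def),
    int_C_Mo = integrate_nodal_field(sys, pr[dof_index(seq_len(sys$n_nodes), 5)]),
    int_C_Ma = integrate_nodal_field(sys, pr[dof_index(seq_len(sys$n_nodes), 6)]),
    int_C_F = integrate_gp_field(sys, state$h[, 1] / sc),
    int_C_SMC = integrate_gp_field(sys, (state$h[, 2] - sys$params$C_smc0) / sc),
    max_collagen_fold_im = max(state$h[im_gp, 3]) / sys$params$rho0_c,
    min_C_N = min(cn),
    min_C_N_plaque = min(cn[plaque_nodes])
  )
}

#' Disease progression phase
#'
#' Starting from the homeostatic state, generates the vasa vasorum network
#' with its occluded mid-vessel band, imposes the nutrient supply (scaled
#' nutrient = 1 on the lumen surface and in every supplied element) and the
#' monocyte recruitment patch, and marches the fully coupled system with
#' adaptive backward-Euler steps over the disease duration.  Summary rows
#' are recorded at every accepted step; snapshot states (and VTU files when
#' `out_dir` is set) at the configured output times.
#'
#' @param home result of [run_homeostasis_phase()].
#' @param config a [simulation_config()]; defaults to the one used for the
#'   preload.
#' @param verbose print per-step progress.
#' @return list with `series` (per-step summary data frame), `summary`
#'   (rows at the output times), `snapshots` (states at output times),
#'   `network`, and the final state.
#' @export
run_disease_phase <- function(home, config = home$config, verbose = FALSE) {
  sys <- home$sys
  mesh <- sys$mesh
  network <- generate_network(mesh, config$vv)
  supplied <- network$supplied_elements

  patch <- monocyte_patch_nodes(mesh, config)
  nut_nodes <- nutrient_dirichlet_nodes(mesh, supplied)
  plaque_nodes <- plaque_region_nodes(sys, config)
  lum_nodes <- unique(as.vector(mesh$facets$lumen))
  zmid <- mesh$geom$length / 2
  dz <- diff(range(mesh$zs)) / sys$mesh$res[3]
  mid_lumen <- lum_nodes[abs(sys$nodes[lum_nodes, 3] - zmid) < dz / 2 + 1e-9]

  dir_all <- combine_dirichlet(
    mechanical_dirichlet(sys, config$axial_stretch),
    dirichlet(dof_index(nut_nodes, 4), config$nutrient_dirichlet_scaled),
    dirichlet(dof_index(patch, 5), config$monocyte_dirichlet_scaled)
  )
  loads <- list(
    pressure = list(facets = mesh$facets$lumen, value = config$p_blood),
    springs = home$springs
  )

  state <- home$state
  state$t <- 0
  out_times <- sort(config$disease$output_days) * DAY
  t_end <- config$disease$duration_days * DAY
  dt <- config$disease$dt0_days * DAY
  dt_min <- config$disease$dt_min_days * DAY
  dt_max <- config$disease$dt_max_days * DAY

  series <- list()
  snapshots <- list()
  io <- !is.null(config$out_dir)
  if (io) dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pvd <- character(0)

  next_out <- 1L
  while (state$t < t_end - 1e-6) {
    target <- if (next_out <= length(out_times)) out_times[next_out] else t_end
    dt_use <- min(dt, dt_max, target - state$t, t_end - state$t)
    st <- time_step(sys, state, dt_use, dir_all, loads,
                    control = newton_control(fd_central = FALSE))
    if (is.null(attr(st, "converged"))) {
      dt <- dt_use / 2
      if (verbose) {
        message("  step rejected at t = ", round(state$t / DAY, 2),
                " d (", st$reason, "), dt -> ", signif(dt / DAY, 3), " d")
      }
      if (dt < dt_min) {
        stop("disease phase: time step underflow at t = ",
             round(state$t / DAY, 2), " days (", st$reason, ")")
      }
      next
    }
    state <- st
    its <- attr(st, "iterations")
    if (its <= 6) dt <- min(dt_use * config$disease$grow, dt_max)
    series[[length(series) + 1]] <-
      summarize_state(sys, state, config, patch, plaque_nodes, mid_lumen)
    if (verbose) {
      message("t = ", round(state$t / DAY, 2), " d (", its, " its)")
    }
    if (next_out <= length(out_times) &&
          abs(state$t - out_times[next_out]) < 1e-6) {
      snapshots[[next_out]] <- state
      if (io) {
        f <- file.path(config$out_dir,
                       sprintf("snapshot_%03d.vtu", next_out))
        write_snapshot(sys, state, f)
        pvd <- c(pvd, f)
      }
      next_out <- next_out + 1L
    }
  }

  series <- do.call(rbind, series)
  summary <- summarize_states(sys, snapshots, config)
  if (io) {
    write_pvd(file.path(config$out_dir, "series.pvd"), pvd,
              out_times / DAY)
    utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    write_metadata(file.path(config$out_dir, "metadata.json"), config)
  }
  list(series = series, summary = summary, snapshots = snapshots,
       network = network, state = state, sys = sys, config = config)
}

#' Summary rows for a list of snapshot states
#'
#' Minimal lumen radius at the mid cross-section (deformed), referential
#' volume integrals of the scaled species, the maximum collagen
#' fold-increase in the intima-media layer, and nutrient minima.
#'
#' @param sys a `fem_system`.
#' @param states list of `system_state` snapshots.
#' @param config the `simulation_config` of the run.
#' @return data frame, one row per snapshot.
#' @export
summarize_states <- function(sys, states, config) {
  mesh <- sys$mesh
  patch <- monocyte_patch_nodes(mesh, config)
  plaque_nodes <- plaque_region_nodes(sys, config)
  lum_nodes <- unique(as.vector(mesh$facets$lumen))
  zmid <- mesh$geom$length / 2
  dz <- mesh$geom$length / mesh$res[3]
  mid_lumen <- lum_nodes[abs(sys$nodes[lum_nodes, 3] - zmid) < dz / 2 + 1e-9]
  do.call(rbind, lapply(states, function(st) {
    summarize_state(sys, st, config, patch, plaque_nodes, mid_lumen)
  }))
}

#' Run both phases
#'
#' @param config a [simulation_config()].
#' @param verbose print progress.
#' @return list with `home` ([run_homeostasis_phase()] result) and `disease`
#'   ([run_disease_phase()] result).
#' @export
run_simulation <- function(config = simulation_config(), verbose = FALSE) {
  home <- run_homeostasis_phase(config, verbose = verbose)
  disease <- run_disease_phase(home, config, verbose = verbose)
  list(home = home, disease = disease)
}
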