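#' Assemble a finite element system
#'
#' Bundles mesh, Gauss-point fiber field and material parameters into the
#' object all solver routines operate on.  Degrees of freedom are node-major
#' with 6 per node: displacement (x, y, z), scaled nutrient, monocyte and
#' macrophage concentrations.  Element-constant pressure and dilatation are
#' condensed exactly at element level and reported per element.
#'
#' @param mesh a `mesh` object.
#' @param fibers a `fiber_field` for this mesh.
#' @param params a [material_params()] object.
#' @return a `fem_system`.
#' @export
fem_system <- function(mesh, fibers, params) {
  stopifnot(inherits(mesh, "mesh"), inherits(fibers, "fiber_field"))
  if (attr(fibers, "n_F") != params$n_F) {
    stop("fiber field has ", attr(fibers, "n_F"), " families but params ",
         "declare n_F = ", params$n_F)
  }
  elems <- mesh$elems
  storage.mode(elems) <- "integer"
  rho00 <- initial_density(params)
  fib <- unclass(fibers)
  attributes(fib) <- attributes(fib)["dim"]
  sys <- list(
    mesh = mesh, params = params, rho00 = rho00,
    nodes = mesh$nodes, elems = elems, fib = fib,
    par_packed = pack_params(params, rho00),
    n_nodes = nrow(mesh$nodes), n_elems = nrow(elems),
    ndof = 6L * nrow(mesh$nodes)
  )
  sys$gp_detj <- cpp_gp_interp(sys$nodes, sys$elems,
                               numeric(sys$n_nodes))[, 1]
  class(sys) <- "fem_system"
  sys
}

#' Degree-of-freedom indices
#'
#' @param node node id (vectorized).
#' @param comp component: 1:3 displacement, 4 scaled nutrient, 5 scaled
#'   monocyte, 6 scaled macrophage concentration.
#' @return integer dof indices.
#' @export
dof_index <- function(node, comp) {
  as.integer(outer(
    (as.integer(node) - 1L) * 6L,
    as.integer(comp), `+`
  ))
}

#' Dirichlet constraint set
#'
#' @param idx dof indices.
#' @param val prescribed values (recycled).
#' @return a `dirichlet` list; combine with [combine_dirichlet()].
#' @export
dirichlet <- function(idx, val = 0) {
  idx <- as.integer(idx)
  val <- rep_len(val, length(idx))
  structure(list(idx = idx, val = val), class = "dirichlet")
}

#' @rdname dirichlet
#' @param ... `dirichlet` objects; later entries override earlier ones on
#'   shared dofs.
#' @export
combine_dirichlet <- function(...) {
  parts <- list(...)
  idx <- unlist(lapply(parts, `[[`, "idx"))
  val <- unlist(lapply(parts, `[[`, "val"))
  keep <- !duplicated(idx, fromLast = TRUE)
  dirichlet(idx[keep], val[keep])
}

#' Fresh solver state
#'
#' @param sys a `fem_system`.
#' @param t initial time, s.
#' @return a `system_state`: primary vector `p` (and previous-step `p_n`),
#'   Gauss-point internal variables `h`, element pressure/dilatation.
#' @export
initialize_state <- function(sys, t = 0) {
  h0 <- matrix(rep(gauss_point_state(sys$params)[1:7],
                   each = 8 * sys$n_elems),
               nrow = 8 * sys$n_elems)
  st <- list(
    t = t, p = numeric(sys$ndof), p_n = numeric(sys$ndof), h = h0,
    p_elem = numeric(sys$n_elems), theta_elem = rep(1, sys$n_elems)
  )
  class(st) <- "system_state"
  st
}

# Dead (reference-configuration) surface traction nodal forces.
traction_forces <- function(sys, facets, tvec) {
  g <- 1 / sqrt(3)
  s2 <- matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), ncol = 2, byrow = TRUE)
  fvec <- numeric(sys$ndof)
  for (k in seq_len(nrow(facets))) {
    pnod <- sys$nodes[facets[k, ], , drop = FALSE]
    for (q in 1:4) {
      xi <- s2[q, 1] * g; eta <- s2[q, 2] * g
      nsh <- 0.25 * (1 + s2[, 1] * xi) * (1 + s2[, 2] * eta)
      dxi <- 0.25 * s2[, 1] * (1 + s2[, 2] * eta)
      deta <- 0.25 * (1 + s2[, 1] * xi) * s2[, 2]
      t1 <- colSums(dxi * pnod)
      t2 <- colSums(deta * pnod)
      da <- sqrt(sum(c(
        t1[2] * t2[3] - t1[3] * t2[2],
        t1[3] * t2[1] - t1[1] * t2[3],
        t1[1] * t2[2] - t1[2] * t2[1]
      )^2))
      for (a in 1:4) {
        dofs <- dof_index(facets[k, a], 1:3)
        fvec[dofs] <- fvec[dofs] + nsh[a] * tvec * da
      }
    }
  }
  fvec
}

#' Radial embedding springs on the outer surface
#'
#' Linear springs acting along the reference radial direction of each outer
#' node, with stiffness scaled by the node's outer-facet multiplicity
#' (corner, edge and interior nodes of the outer surface carry 1x, 2x and 4x
#' the base stiffness).
#'
#' @param sys a `fem_system` built on an annulus mesh.
#' @param k_base base stiffness, N/m (per single-facet node).
#' @return springs load specification.
#' @export
outer_surface_springs <- function(sys, k_base) {
  mult <- sys$mesh$outer_multiplicity
  nodes <- as.integer(names(mult))
  xy <- sys$nodes[nodes, 1:2, drop = FALSE]
  rr <- sqrt(rowSums(xy^2))
  dirs <- cbind(xy / rr, 0)
  list(nodes = nodes, k = k_base * as.numeric(mult), dirs = dirs)
}

# Assemble residual (and optionally the consistent tangent) of the full
# coupled system at trial primaries p, previous-step primaries p_n and
# previous-step internal variables h_n.
assemble_system <- function(sys, p, p_n, h_n, dt, loads = list(),
                            want_tangent = FALSE, fd_eps = 1e-7,
                            fd_central = TRUE) {
  core <- fem_assemble(sys$nodes, sys$elems, p, p_n, h_n, sys$fib,
                       sys$par_packed, dt, want_tangent, fd_eps, fd_central)
  if (!core$ok) return(list(ok = FALSE))
  R <- core$R
  ti <- list(core$i); tj <- list(core$j); tx <- list(core$x)
  if (!is.null(loads$pressure) && loads$pressure$value != 0) {
    facets <- loads$pressure$facets
    storage.mode(facets) <- "integer"
    pl <- fem_pressure_load(sys$nodes, facets, p, loads$pressure$value,
                            want_tangent, fd_eps)
    R <- R + pl$R
    if (want_tangent) {
      ti <- c(ti, list(pl$i)); tj <- c(tj, list(pl$j))
      tx <- c(tx, list(pl$x))
    }
  }
  if (!is.null(loads$springs)) {
    sp <- loads$springs
    du <- sapply(1:3, function(c) p[dof_index(sp$nodes, c)])
    if (is.null(dim(du))) du <- matrix(du, nrow = 1)
    ud <- rowSums(du * sp$dirs)
    for (a in 1:3) {
      idx <- dof_index(sp$nodes, a)
      R[idx] <- R[idx] + sp$k * ud * sp$dirs[, a]
    }
    if (want_tangent) {
      for (a in 1:3) {
        for (b in 1:3) {
          ti <- c(ti, list(dof_index(sp$nodes, a)))
          tj <- c(tj, list(dof_index(sp$nodes, b)))
          tx <- c(tx, list(sp$k * sp$dirs[, a] * sp$dirs[, b]))
        }
      }
    }
  }
  if (!is.null(loads$traction)) {
    R <- R - traction_forces(sys, loads$traction$facets, loads$traction$t)
  }
  out <- list(ok = TRUE, R = R, h_new = core$h_new, p_elem = core$p_elem,
              theta_elem = core$theta_elem)
  if (want_tangent) {
    # triplet aggregation via dgTMatrix (duplicates are summed on coercion);
    # far cheaper than Matrix::sparseMatrix for repeated assemblies
    kt <- methods::new("dgTMatrix",
                       i = unlist(ti, use.names = FALSE) - 1L,
                       j = unlist(tj, use.names = FALSE) - 1L,
                       x = unlist(tx, use.names = FALSE),
                       Dim = c(sys$ndof, sys$ndof))
    out$K <- methods::as(kt, "CsparseMatrix")
  }
  out
}

#' Global residual of the coupled system
#'
#' Standard Bubnov-Galerkin weak forms with 2x2x2 Gauss quadrature:
#' mechanical stress divergence with condensed element pressure/dilatation,
#' follower lumen pressure, radial springs; steady nutrient
#' diffusion-reaction; backward-Euler monocyte and macrophage
#' diffusion-advection-reaction rows.  Gauss-point internal variables are
#' re-solved from their previous-step values at the trial primaries before
#' stress evaluation.
#'
#' @param sys a `fem_system`.
#' @param p trial primary vector at `t + dt`.
#' @param p_n converged primary vector at `t`.
#' @param h_n Gauss-point internal variables at `t`.
#' @param dt time step, s.
#' @param loads list with optional `pressure` (`list(facets, value)`,
#'   follower), `springs` (see [outer_surface_springs()]) and `traction`
#'   (`list(facets, t)`, dead).
#' @return list with `R`, updated internal variables `h_new`, `p_elem`,
#'   `theta_elem`, and `ok` (`FALSE` on an inverted element).
#' @export
assemble_residual <- function(sys, p, p_n, h_n, dt, loads = list()) {
  assemble_system(sys, p, p_n, h_n, dt, loads, want_tangent = FALSE)
}

#' Consistent global tangent
#'
#' Derivative of [assemble_residual()] with respect to the primaries,
#' including the internal-variable sensitivity (the element residual map
#' re-solves the Gauss-point variables, so `dh/dp` is embedded), the
#' follower-pressure geometric term and the spring stiffness.  Assembled per
#' element by central finite differencing of the analytic element residual.
#'
#' @inheritParams assemble_residual
#' @param fd_eps relative perturbation of the element-level differencing.
#' @return list with sparse matrix `K` plus the [assemble_residual()] fields.
#' @export
assemble_tangent <- function(sys, p, p_n, h_n, dt, loads = list(),
                             fd_eps = 1e-7, fd_central = TRUE) {
  assemble_system(sys, p, p_n, h_n, dt, loads, want_tangent = TRUE,
                  fd_eps = fd_eps, fd_central = fd_central)
}

#' Newton solver controls
#'
#' @param atol absolute 2-norm tolerance on the free-dof residual.
#' @param rtol relative tolerance versus the first iterate's residual.
#' @param max_iter maximum Newton iterations.
#' @param fd_eps element-level differencing perturbation.
#' @param max_ls maximum residual-halving line-search cuts.
#' @param nonmono bounded residual-increase factor accepted when every
#'   line-search cut fails (escape hatch for non-smooth Macaulay branches).
#' @param fd_central use central (default) or one-sided forward differencing
#'   for the element tangent; forward halves the assembly cost at a tangent
#'   accuracy still far below the Newton tolerance.
#' @return control list.
#' @export
newton_control <- function(atol = 1e-8, rtol = 1e-10, max_iter = 25,
                           fd_eps = 1e-7, max_ls = 6, nonmono = 5,
                           fd_central = TRUE) {
  list(atol = atol, rtol = rtol, max_iter = max_iter, fd_eps = fd_eps,
       max_ls = max_ls, nonmono = nonmono, fd_central = fd_central)
}

#' Solve one nonlinear system with Newton's method
#'
#' Dirichlet constraints are imposed by value substitution and row/column
#' elimination; the sparse linearized systems are solved by direct LU
#' factorization.  A backtracking line search guards strongly nonlinear
#' steps; an inverted element or a singular tangent reports failure so the
#' caller can reject the time step.
#'
#' @param sys a `fem_system`.
#' @param p_init initial guess for the primaries.
#' @param p_n previous-step primaries.
#' @param h_n previous-step internal variables.
#' @param dt time step, s.
#' @param dirich a [dirichlet()] constraint set.
#' @param loads load list (see [assemble_residual()]).
#' @param control a [newton_control()].
#' @return list with `converged`, `p`, `h`, `p_elem`, `theta_elem`,
#'   `iterations`, `residual_history`, and `reason` on failure.
#' @export
newton_solve <- function(sys, p_init, p_n, h_n, dt, dirich,
                         loads = list(), control = newton_control()) {
  p <- p_init
  if (length(dirich$idx)) p[dirich$idx] <- dirich$val
  free <- setdiff(seq_len(sys$ndof), dirich$idx)
  hist <- numeric(0)
  r0 <- NULL
  for (it in seq_len(control$max_iter)) {
    asm <- assemble_system(sys, p, p_n, h_n, dt, loads, want_tangent = TRUE,
                           fd_eps = control$fd_eps,
                           fd_central = control$fd_central)
    if (!asm$ok) {
      return(list(converged = FALSE, reason = "inverted_element", p = p,
                  residual_history = hist))
    }
    rf <- asm$R[free]
    rn <- sqrt(sum(rf^2))
    hist <- c(hist, rn)
    if (is.null(r0)) r0 <- max(rn, 1e-300)
    if (rn < control$atol || rn / r0 < control$rtol) {
      return(list(converged = TRUE, p = p, h = asm$h_new,
                  p_elem = asm$p_elem, theta_elem = asm$theta_elem,
                  iterations = it - 1L, residual_history = hist))
    }
    dp <- tryCatch(
      -as.numeric(Matrix::solve(asm$K[free, free, drop = FALSE], rf)),
      error = function(e) NULL
    )
    if (is.null(dp) || any(!is.finite(dp))) {
      return(list(converged = FALSE, reason = "singular_tangent", p = p,
                  residual_history = hist))
    }
    step <- 1
    accepted <- FALSE
    best <- NULL
    for (ls in seq_len(control$max_ls)) {
      ptrial <- p
      ptrial[free] <- p[free] + step * dp
      chk <- assemble_system(sys, ptrial, p_n, h_n, dt, loads,
                             want_tangent = FALSE)
      if (chk$ok) {
        rn2 <- sqrt(sum(chk$R[free]^2))
        if (is.null(best) || rn2 < best$rn) {
          best <- list(p = ptrial, rn = rn2)
        }
        # accept a full step unless it blows the residual up; backtrack
        # otherwise until it decreases
        if (rn2 <= (if (ls == 1) 2 else 1) * rn || rn2 < control$atol) {
          p <- ptrial
          accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!accepted) {
      # nonmonotone escape: the Macaulay kinks (fiber tension switch,
      # collagen cap, plaque-size clamp) can force a transient residual
      # increase; accept a bounded one and let later iterations settle
      # the branch assignment
      if (!is.null(best) && best$rn <= control$nonmono * rn) {
        p <- best$p
        accepted <- TRUE
      } else {
        return(list(converged = FALSE, reason = "line_search_failure",
                    p = p, residual_history = hist))
      }
    }
  }
  list(converged = FALSE, reason = "max_iterations", p = p,
       residual_history = hist)
}

#' Advance the coupled system by one backward-Euler step
#'
#' @param sys a `fem_system`.
#' @param state a `system_state` at time `t`.
#' @param dt time step, s.
#' @param dirich Dirichlet set for the new time level.
#' @param loads load list.
#' @param control a [newton_control()].
#' @return on success, the new `system_state` at `t + dt` (with
#'   `iterations` attached); on failure a list with `converged = FALSE` for
#'   the caller's step-size controller.
#' @export
time_step <- function(sys, state, dt, dirich, loads = list(),
                      control = newton_control()) {
  stopifnot(dt > 0)
  sol <- newton_solve(sys, state$p, state$p_n, state$h, dt, dirich, loads,
                      control)
  if (!sol$converged) return(sol)
  new_state <- list(
    t = state$t + dt, p = sol$p, p_n = sol$p, h = sol$h,
    p_elem = sol$p_elem, theta_elem = sol$theta_elem
  )
  class(new_state) <- "system_state"
  attr(new_state, "iterations") <- sol$iterations
  attr(new_state, "converged") <- TRUE
  new_state
}

#' Integrate a nodal field over the reference mesh
#'
#' @param sys a `fem_system`.
#' @param nodal per-node values.
#' @return scalar integral (2x2x2 Gauss quadrature).
#' @export
integrate_nodal_field <- function(sys, nodal) {
  gp <- cpp_gp_interp(sys$nodes, sys$elems, as.numeric(nodal))
  sum(gp[, 1] * gp[, 2])
}

#' Integrate a per-Gauss-point field over the reference mesh
#'
#' @param sys a `fem_system`.
#' @param values one value per Gauss point (element-major, 8 per element).
#' @return scalar integral.
#' @export
integrate_gp_field <- function(sys, values) {
  sum(sys$gp_detj * values)
}

#' Per-Gauss-point kinematic and constitutive report
#'
#' @param sys a `fem_system`.
#' @param state a `system_state`.
#' @return data frame with columns `J`, `rho0`, `f_rho`, `detJ0`,
#'   `lambda_e1..n_F` (elastic fiber stretches) and `svm` (von Mises Cauchy
#'   stress), one row per Gauss point.
#' @export
gp_report <- function(sys, state) {
  m <- cpp_gp_report(sys$nodes, sys$elems, state$p, state$h, sys$fib,
                     sys$par_packed, state$p_elem)
  nf <- sys$params$n_F
  df <- as.data.frame(m)
  names(df) <- c("J", "rho0", "f_rho", "detJ0",
                 paste0("lambda_e", seq_len(nf)), "svm")
  df$element <- rep(seq_len(sys$n_elems), each = 8)
  df
}
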