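#' Material and kinetic parameters
#'
#' Bundles every constitutive, remodeling, growth and species parameter of the
#' coupled model, all in SI units.  Mechanical energy parameters are specified
#' per unit mass (J/kg) and multiplied by the relevant reference mass density
#' inside the strain energy, so that changes of mass translate directly into
#' changes of stored energy and, through the volumetric coupling term, into
#' growth.
#'
#' Defaults are the package's documented study conditions: geometry, loads,
#' concentration scales and the collagen cap `K_c = 5` follow the published
#' description of the scenario; the remaining rates and moduli are package
#' defaults chosen by time-scale analysis (see the methods vignette) and carry
#' provenance `"decision-default"` in the config metadata.
#'
#' @param mu matrix (elastin-dominated ground substance) stiffness, J/kg.
#' @param k1,k2 collagen fiber stiffness (J/kg) and dimensionless exponent of
#'   the exponential fiber energy.  Fibers carry load only in tension.
#' @param kappa volumetric penalty, J/kg; enforces that the Jacobian follows
#'   the relative mass increase (incompressible growth in the limit).
#' @param k_r remodeling rate of the collagen remodeling stretch, 1/s.
#' @param lambda_pre collagen deposition prestretch (= homeostatic elastic
#'   stretch), dimensionless, must exceed 1.001.
#' @param alpha mass of a single cell, kg/cell.
#' @param phi_c mass fractions of the `n_F` collagen fiber families; must sum
#'   to 1.
#' @param r_c collagen production rate per excess smooth muscle cell,
#'   kg/(cells/m^3)/s per unit reference volume.
#' @param K_c collagen cap: maximum collagen density relative to the initial
#'   reference density, dimensionless, >= 1.
#' @param r_smc smooth-muscle-cell attraction rate per foam cell, 1/s.
#' @param E_MoMa monocyte-to-macrophage differentiation rate, 1/s.
#' @param E_MaF macrophage-to-foam-cell transformation rate, 1/s.
#' @param a_Mo monocyte apoptosis rate, 1/s.
#' @param rho0_m,rho0_c initial matrix and collagen reference densities,
#'   kg/m^3.
#' @param C_smc0 initial smooth muscle cell concentration, cells/m^3.
#' @param rho_tilde total mass ratio at which nutrient diffusivity reaches its
#'   minimum, dimensionless, > 1.
#' @param D_N_min,D_N_max nutrient diffusivity range, m^2/s.
#' @param D_Mo,D_Ma monocyte and macrophage diffusivities, m^2/s.
#' @param r_Mo,r_Ma chemotactic mobilities (advective velocity per nutrient
#'   gradient), m^5/(kg s).
#' @param R_N constant nutrient consumption rate, kg/(m^3 s).
#' @param n_F number of collagen fiber families.
#' @param scale_N,scale_cell concentration scales used for the nutrient and
#'   cell degrees of freedom (physical = scaled x scale).
#' @param k_cm_N,k_cm_Mo,k_cm_Ma residual row scalings for the species
#'   equations.  They equilibrate the magnitude of the concentration residual
#'   rows against the mechanical rows and provably do not affect the converged
#'   solution.
#'
#' @return An object of class `material_params` (a validated list).
#' @export
material_params <- function(mu = 30,
                            k1 = 200,
                            k2 = 10,
                            kappa = 5e4,
                            k_r = 1e-6,
                            lambda_pre = 1.1,
                            alpha = 1e-13,
                            phi_c = NULL,
                            r_c = 5e-18,
                            K_c = 5,
                            r_smc = 1e-7,
                            E_MoMa = 5e-7,
                            E_MaF = 5e-7,
                            a_Mo = 5e-7,
                            rho0_m = 900,
                            rho0_c = 150,
                            C_smc0 = 1e13,
                            rho_tilde = 1.5,
                            D_N_min = 2e-10,
                            D_N_max = 1e-9,
                            D_Mo = 5e-11,
                            D_Ma = 5e-11,
                            r_Mo = 5e-6,
                            r_Ma = 5e-6,
                            R_N = 3e-11,
                            n_F = 4L,
                            scale_N = 1e-5,
                            scale_cell = 1e13,
                            k_cm_N = 1e11,
                            k_cm_Mo = 1e11,
                            k_cm_Ma = 1e11) {
  if (is.null(phi_c)) phi_c <- rep(1 / n_F, n_F)
  p <- list(
    mu = mu, k1 = k1, k2 = k2, kappa = kappa, k_r = k_r,
    lambda_pre = lambda_pre, alpha = alpha, phi_c = phi_c, r_c = r_c,
    K_c = K_c, r_smc = r_smc, E_MoMa = E_MoMa, E_MaF = E_MaF, a_Mo = a_Mo,
    rho0_m = rho0_m, rho0_c = rho0_c, C_smc0 = C_smc0,
    rho_tilde = rho_tilde, D_N_min = D_N_min, D_N_max = D_N_max,
    D_Mo = D_Mo, D_Ma = D_Ma, r_Mo = r_Mo, r_Ma = r_Ma, R_N = R_N,
    n_F = as.integer(n_F), scale_N = scale_N, scale_cell = scale_cell,
    k_cm_N = k_cm_N, k_cm_Mo = k_cm_Mo, k_cm_Ma = k_cm_Ma
  )
  validate_material_params(p)
  class(p) <- "material_params"
  p
}

validate_material_params <- function(p) {
  stopifnot(
    p$mu > 0, p$k1 >= 0, p$k2 > 0, p$kappa > 0,
    p$alpha > 0, p$rho0_m > 0, p$rho0_c >= 0, p$C_smc0 >= 0,
    p$D_N_min > 0, p$D_N_max >= p$D_N_min,
    p$D_Mo >= 0, p$D_Ma >= 0,
    p$k_r >= 0, p$r_c >= 0, p$r_smc >= 0,
    p$E_MoMa >= 0, p$E_MaF >= 0, p$a_Mo >= 0, p$R_N >= 0,
    p$n_F >= 1, length(p$phi_c) == p$n_F,
    p$scale_N > 0, p$scale_cell > 0,
    p$k_cm_N > 0, p$k_cm_Mo > 0, p$k_cm_Ma > 0
  )
  if (p$K_c < 1) {
    stop("K_c must be >= 1 (collagen cap relative to initial density)")
  }
  if (p$lambda_pre <= 1 + 1e-3) {
    stop("lambda_pre must exceed 1.001: the remodeling rate is normalized ",
         "by (lambda_pre - 1), which degenerates as lambda_pre -> 1")
  }
  if (p$rho_tilde <= 1) {
    stop("rho_tilde must exceed 1 (plaque size function denominator)")
  }
  if (abs(sum(p$phi_c) - 1) > 1e-12) {
    stop("collagen family mass fractions phi_c must sum to 1")
  }
  invisible(p)
}

#' Initial total reference density rho0(0)
#'
#' Frozen once at configuration time: matrix + collagen + cell mass at the
#' initial concentrations.  The volumetric growth term always measures mass
#' relative to this value.
#'
#' @param params a [material_params()] object.
#' @param C_Mo0,C_Ma0,C_F0 initial concentrations, cells/m^3 (defaults 0).
#' @return scalar, kg/m^3.
#' @export
initial_density <- function(params, C_Mo0 = 0, C_Ma0 = 0, C_F0 = 0) {
  params$rho0_m + params$rho0_c +
    params$alpha * (C_Mo0 + C_Ma0 + C_F0 + params$C_smc0)
}

# Fixed-order numeric packing consumed by the C++ kernels.
pack_params <- function(p, rho00 = NULL) {
  if (is.null(rho00)) rho00 <- initial_density(p)
  c(p$mu, p$k1, p$k2, p$kappa, p$k_r, p$lambda_pre, p$alpha, p$r_c, p$K_c,
    p$r_smc, p$E_MoMa, p$E_MaF, p$a_Mo, p$rho0_m, p$rho0_c, p$C_smc0,
    p$rho_tilde, p$D_N_min, p$D_N_max, p$D_Mo, p$D_Ma, p$r_Mo, p$r_Ma,
    p$R_N, rho00, p$scale_N, p$scale_cell, p$k_cm_N, p$k_cm_Mo, p$k_cm_Ma,
    p$n_F, p$phi_c)
}

#' Fresh Gauss-point internal state
#'
#' Internal variables at one material point: foam cell and smooth muscle cell
#' concentrations, collagen reference density, and one remodeling stretch per
#' fiber family.  The remodeling stretches start at 1; the homeostatic preload
#' phase evolves them until the elastic fiber stretches reach the deposition
#' prestretch.
#'
#' @param params a [material_params()] object.
#' @return named numeric vector of length `3 + n_F`.
#' @export
gauss_point_state <- function(params) {
  stats::setNames(
    c(0, params$C_smc0, params$rho0_c, rep(1, params$n_F)),
    c("C_F", "C_SMC", "rho0_c", paste0("lambda_r", seq_len(params$n_F)))
  )
}
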