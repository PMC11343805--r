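#' Plaque size function
#'
#' Normalized measure of local mass increase,
#' `f_rho = <rho_tilde - rho0/rho0(0)> / (rho_tilde - 1)`, clamped to
#' `[0, 1]`: 1 in healthy tissue (`rho0 = rho0(0)`), 0 once the mass ratio
#' reaches `rho_tilde`.  It linearly throttles the nutrient diffusivity as
#' the plaque densifies.
#'
#' @param rho0_ratio current-to-initial reference density ratio.
#' @param rho_tilde mass ratio of minimal diffusion, > 1.
#' @return value in `[0, 1]` (vectorized).
#' @export
plaque_size_function <- function(rho0_ratio, rho_tilde) {
  if (any(rho_tilde <= 1)) stop("rho_tilde must exceed 1")
  pmin(1, pmax(0, (rho_tilde - rho0_ratio) / (rho_tilde - 1)))
}

#' Nutrient diffusivity
#'
#' Linear interpolation between the occluded-plaque minimum and the
#' healthy-tissue maximum: `D_N = (1 - f_rho) D_min + f_rho D_max`.
#'
#' @param f_rho plaque size function value in `[0, 1]`.
#' @param D_N_min,D_N_max diffusivity bounds, m^2/s.
#' @return diffusivity, m^2/s (vectorized).
#' @export
nutrient_diffusivity <- function(f_rho, D_N_min, D_N_max) {
  stopifnot(all(f_rho >= 0), all(f_rho <= 1), D_N_min > 0,
            D_N_max >= D_N_min)
  (1 - f_rho) * D_N_min + f_rho * D_N_max
}

#' Referential nutrient flux and reaction
#'
#' Steady diffusion-reaction law on the reference configuration: flux
#' `A_N = D_N J C^-1 grad_X(C_N)` (pull-back of the spatial Fick flux through
#' the deformation `F`, `C = F^T F`) and constant consumption `R_N`.
#'
#' @param grad_C_N referential nutrient gradient (length 3).
#' @param F deformation gradient.
#' @param D_N diffusivity, m^2/s.
#' @param R_N consumption rate, kg/(m^3 s).
#' @return list with `flux` (length 3) and `reaction` (scalar, the constant
#'   sink entering the steady balance `div(A_N) - R_N = 0`).
#' @export
nutrient_flux_reaction <- function(grad_C_N, F, D_N, R_N) {
  J <- det(F)
  if (J <= 0) stop("inverted state: det(F) <= 0")
  Ci <- solve(t(F) %*% F)
  list(flux = as.numeric(D_N * J * Ci %*% grad_C_N), reaction = R_N)
}

#' Referential monocyte flux and reaction
#'
#' Diffusion-advection-reaction law for monocytes: diffusive flux
#' `D_Mo J C^-1 grad(C_Mo)` minus the chemotactic term
#' `r_Mo C_Mo C^-1 grad(C_N)` (inside the divergence; the physical advective
#' cell flux is `+ r_Mo C_Mo grad(C_N)`, i.e. toward higher nutrient
#' concentration), with differentiation to macrophages and apoptosis as
#' sinks.
#'
#' @param C_Mo monocyte concentration.
#' @param grad_C_Mo,grad_C_N referential gradients (length 3).
#' @param C_Mo_dot time derivative of `C_Mo` (e.g. backward-Euler quotient).
#' @param F deformation gradient.
#' @param params a [material_params()] object.
#' @return list with `flux` (the divergence-side vector `A_Mo`),
#'   `advective_flux` (physical chemotactic cell flux), and `reaction`
#'   (`C_Mo_dot + (E_MoMa + a_Mo) C_Mo`).
#' @export
monocyte_flux_reaction <- function(C_Mo, grad_C_Mo, grad_C_N, C_Mo_dot, F,
                                   params) {
  J <- det(F)
  if (J <= 0) stop("inverted state: det(F) <= 0")
  Ci <- solve(t(F) %*% F)
  adv <- as.numeric(params$r_Mo * C_Mo * Ci %*% grad_C_N)
  list(
    flux = as.numeric(params$D_Mo * J * Ci %*% grad_C_Mo) - adv,
    advective_flux = adv,
    reaction = C_Mo_dot + (params$E_MoMa + params$a_Mo) * C_Mo
  )
}

#' Referential macrophage flux and reaction
#'
#' As [monocyte_flux_reaction()] with diffusivity `D_Ma` and chemotaxis
#' `r_Ma`; the reaction gains mass from monocyte differentiation and loses it
#' to foam-cell transformation:
#' `C_Ma_dot - E_MoMa C_Mo + E_MaF C_Ma`.
#'
#' @param C_Ma macrophage concentration.
#' @param grad_C_Ma,grad_C_N referential gradients.
#' @param C_Ma_dot time derivative of `C_Ma`.
#' @param C_Mo monocyte concentration (differentiation source).
#' @param F deformation gradient.
#' @param params a [material_params()] object.
#' @return list with `flux`, `advective_flux`, `reaction`.
#' @export
macrophage_flux_reaction <- function(C_Ma, grad_C_Ma, grad_C_N, C_Ma_dot,
                                     C_Mo, F, params) {
  J <- det(F)
  if (J <= 0) stop("inverted state: det(F) <= 0")
  Ci <- solve(t(F) %*% F)
  adv <- as.numeric(params$r_Ma * C_Ma * Ci %*% grad_C_N)
  list(
    flux = as.numeric(params$D_Ma * J * Ci %*% grad_C_Ma) - adv,
    advective_flux = adv,
    reaction = C_Ma_dot - params$E_MoMa * C_Mo + params$E_MaF * C_Ma
  )
}

#' Concentration scaling
#'
#' The solver carries concentrations in scaled form: nutrients relative to
#' 1e-5 kg/m^3, cell species relative to 1e13 cells/m^3.
#'
#' @param physical named list/vector with any of `C_N`, `C_Mo`, `C_Ma`,
#'   `C_F`, `C_SMC` in physical units.
#' @param params a [material_params()] object (holds the scales).
#' @return list of scaled values.
#' @export
scale_concentrations <- function(physical, params = material_params()) {
  physical <- as.list(physical)
  lapply(stats::setNames(nm = names(physical)), function(nm) {
    s <- if (nm == "C_N") params$scale_N else params$scale_cell
    physical[[nm]] / s
  })
}

#' @rdname scale_concentrations
#' @param scaled list/vector of scaled values.
#' @export
unscale_concentrations <- function(scaled, params = material_params()) {
  scaled <- as.list(scaled)
  lapply(stats::setNames(nm = names(scaled)), function(nm) {
    s <- if (nm == "C_N") params$scale_N else params$scale_cell
    scaled[[nm]] * s
  })
}
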