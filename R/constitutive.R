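#' Remodeling deformation gradient of a fiber family
#'
#' Isochoric inelastic deformation representing collagen turnover along the
#' (referential) fiber direction `a`:
#' `F_r = lambda_r a (x) a + lambda_r^(-1/2) (I - a (x) a)`, so
#' `det(F_r) = 1` exactly.
#'
#' @param lambda_r remodeling stretch, > 0.
#' @param a unit fiber direction (length 3).
#' @return 3 x 3 matrix.
#' @export
remodeling_tensor <- function(lambda_r, a) {
  stopifnot(length(a) == 3, abs(sum(a^2) - 1) < 1e-8)
  if (lambda_r <= 0) stop("remodeling stretch must be positive")
  cpp_remodeling_tensor(lambda_r, a)
}

#' Elastic kinematic measures at a material point
#'
#' Splits the deformation gradient multiplicatively per fiber family,
#' `F = F_e^cj F_r^cj`, and evaluates the elastic fiber invariants
#' `I4e = C_e : (a (x) a) = (lambda / lambda_r)^2` together with the
#' isochoric first invariant of the purely elastic matrix.
#'
#' @param F deformation gradient (3 x 3), `det(F) > 0`.
#' @param state Gauss-point state vector (see [gauss_point_state()]), or a
#'   vector of remodeling stretches.
#' @param fibers `n_F x 3` matrix of unit fiber directions.
#' @return list with `J`, `I1bar`, `I4e`, `lambda_e`, `lambda_total`.
#' @export
elastic_measures <- function(F, state, fibers) {
  lr <- if (length(state) > nrow(fibers)) {
    state[3 + seq_len(nrow(fibers))]
  } else {
    state
  }
  out <- cpp_elastic_measures(F, as.numeric(lr), as.matrix(fibers))
  lapply(out, as.numeric)
}

#' Strain energy density (per unit reference volume)
#'
#' Three-field mixed form: deviatoric neo-Hookean matrix scaled by the matrix
#' mass density, exponential tension-only fiber terms scaled by the per-family
#' collagen densities, and the volumetric growth coupling
#' `rho0 (kappa/2 (theta - rho0/rho0(0))^2 + p (J - theta))` that drives the
#' Jacobian toward the relative mass increase.
#'
#' @param F deformation gradient.
#' @param state Gauss-point state vector.
#' @param fibers `n_F x 3` fiber direction matrix.
#' @param theta element dilatation (> 0).
#' @param p element pressure (Pa).
#' @param params a [material_params()] object.
#' @param C_Mo,C_Ma monocyte/macrophage concentrations at the point,
#'   physical cells/m^3.
#' @param rho00 initial total reference density; default from `params`.
#' @return scalar energy density, J/m^3.
#' @export
energy_density <- function(F, state, fibers, theta, p, params,
                           C_Mo = 0, C_Ma = 0, rho00 = NULL) {
  if (theta <= 0) stop("element dilatation theta must be positive")
  cpp_energy_density(F, as.numeric(state)[1:7], as.matrix(fibers), theta, p,
                     C_Mo, C_Ma, pack_params(params, rho00))
}

#' First Piola-Kirchhoff and Cauchy stress
#'
#' Exact derivative of [energy_density()] with respect to `F` at fixed
#' internal variables, pressure and dilatation; the Cauchy stress follows by
#' push-forward `sigma = J^-1 P F^T`.
#'
#' @inheritParams energy_density
#' @return list with `P` (3 x 3) and `sigma` (3 x 3, symmetric).
#' @export
pk1_and_cauchy_stress <- function(F, state, fibers, theta, p, params,
                                  C_Mo = 0, C_Ma = 0, rho00 = NULL) {
  P <- cpp_pk1(F, as.numeric(state)[1:7], as.matrix(fibers), theta, p,
               C_Mo, C_Ma, pack_params(params, rho00))
  J <- det(F)
  sig <- P %*% t(F) / J
  list(P = P, sigma = sig)
}

#' Backward-Euler update of the Gauss-point internal variables
#'
#' Advances foam cells (`C_F`), smooth muscle cells (`C_SMC`), collagen
#' density (`rho0_c`, implicit with its Macaulay cap) and the per-family
#' remodeling stretches (`lambda_r`, scalar Newton per family driven by the
#' gap between elastic stretch and deposition prestretch) over one time step:
#'
#' * `C_F^{n+1}  = C_F^n + dt E_MaF C_Ma^{n+1}`
#' * `C_SMC^{n+1} = C_SMC^n + dt r_smc C_F^{n+1}`
#' * `rho0_c^{n+1} = rho0_c^n + dt r_c (C_SMC^{n+1} - C_smc0)
#'      <1 - rho0_c^{n+1} / (K_c rho0_c(0))>`
#' * `lambda_r^{n+1} = lambda_r^n + dt k_r (lambda_e^{n+1} - lambda_pre) /
#'      (lambda_pre - 1)` with `lambda_e = lambda / lambda_r`.
#'
#' @param state_n internal state at `t_n` (see [gauss_point_state()]).
#' @param F_new deformation gradient at `t_{n+1}`.
#' @param C_Ma_new macrophage concentration at `t_{n+1}`, physical cells/m^3.
#' @param dt time step, s.
#' @param fibers `n_F x 3` fiber direction matrix.
#' @param params a [material_params()] object.
#' @return updated state vector.
#' @export
update_internal_variables <- function(state_n, F_new, C_Ma_new, dt, fibers,
                                      params) {
  stopifnot(dt >= 0)
  out <- cpp_update_h(as.numeric(state_n)[1:7], F_new, as.matrix(fibers),
                      C_Ma_new, dt, pack_params(params))
  stats::setNames(as.numeric(out), names(gauss_point_state(params)))
}

#' Composition bookkeeping at a material point
#'
#' Converts cell concentrations into reference mass densities (constant mass
#' `alpha` per cell) and totals the tissue reference density
#' `rho0 = rho0_m + rho0_c + rho0_cells`.
#'
#' @param state internal state vector (`C_F`, `C_SMC`, `rho0_c`, ...).
#' @param C_Mo,C_Ma diffusive cell concentrations, physical cells/m^3.
#' @param params a [material_params()] object.
#' @return list with `rho0_cells` and `rho0` (kg/m^3).
#' @export
composition <- function(state, C_Mo, C_Ma, params) {
  rho_cells <- params$alpha * (C_Mo + C_Ma + state[["C_F"]] + state[["C_SMC"]])
  list(rho0_cells = rho_cells,
       rho0 = params$rho0_m + state[["rho0_c"]] + rho_cells)
}
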