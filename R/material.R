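#' Material and damping parameters
#'
#' Isotropic linear-elastic material for the kidney plus Rayleigh damping.
#' Defaults are the soft-tissue values used by the simulator: Young's
#' modulus 0.1 MPa and Poisson's ratio 0.3; density 1050 kg/m^3 (typical
#' renal parenchyma); mass- and stiffness-proportional damping chosen for
#' visibly damped, stable interaction.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson's ratio, in `[0, 0.5)`.
#' @param rho density (kg/m^3).
#' @param rayleigh_alpha mass-proportional damping (1/s).
#' @param rayleigh_beta stiffness-proportional damping (s).
#' @return An object of class `material_params`.
#' @export
material_params <- function(E = 1e5, nu = 0.3, rho = 1050,
                            rayleigh_alpha = 1.0, rayleigh_beta = 0.01) {
  if (!is.numeric(E) || length(E) != 1L || E <= 0) stopf("E must be > 0 Pa")
  if (!is.numeric(nu) || length(nu) != 1L || nu < 0 || nu >= 0.5)
    stopf("nu must lie in [0, 0.5)")
  if (rho <= 0) stopf("rho must be > 0")
  if (rayleigh_alpha < 0 || rayleigh_beta < 0)
    stopf("damping coefficients must be >= 0")
  structure(list(E = E, nu = nu, rho = rho,
                 rayleigh_alpha = rayleigh_alpha, rayleigh_beta = rayleigh_beta),
            class = "material_params")
}
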