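#' Young's modulus from surface (Rayleigh) wave group velocity
#'
#' `E = 2 rho (1 + nu)^3 / (0.87 + 1.12 nu)^2 * Cg^2`, the standard
#' Rayleigh-wave relation for a semi-infinite elastic half-space, used for
#' surface-wave elastography.
#'
#' @param Cg Surface wave group velocity (m/s, > 0).
#' @param nu Poisson's ratio in `[0, 0.5]`.
#' @param rho Mass density (kg/m^3, > 0), default 1000.
#' @return An `elasticity_result`: `young_modulus` (Pa), `model`,
#'   `input_speed`, `poisson_ratio`, `density`.
#' @export
ym_rayleigh <- function(Cg, nu = 0.5, rho = 1000) {
  if (!is.finite(Cg) || Cg <= 0) stop("Cg must be positive")
  if (nu < 0 || nu > 0.5) stop("nu must lie in [0, 0.5]")
  if (rho <= 0) stop("rho must be positive")
  E <- 2 * rho * (1 + nu)^3 / (0.87 + 1.12 * nu)^2 * Cg^2
  structure(list(young_modulus = E, model = "rayleigh_surface",
                 input_speed = Cg, poisson_ratio = nu, density = rho),
            class = "elasticity_result")
}

#' Young's modulus from shear wave group velocity
#'
#' `E = 3 rho c^2`, the incompressible-limit shear-wave relation used for
#' ultrasound shear wave elastography.
#'
#' @param c Shear wave group velocity (m/s, > 0).
#' @param rho Mass density (kg/m^3, > 0), default 1000.
#' @return An `elasticity_result`.
#' @export
ym_shear <- function(c, rho = 1000) {
  if (!is.finite(c) || c <= 0) stop("c must be positive")
  if (rho <= 0) stop("rho must be positive")
  structure(list(young_modulus = 3 * rho * c^2, model = "shear",
                 input_speed = c, poisson_ratio = 0.5, density = rho),
            class = "elasticity_result")
}

#' Rayleigh-to-shear wave speed ratio
#'
#' The ratio `c_R / c_s` of Rayleigh surface wave speed to bulk shear wave
#' speed. `"exact_secular"` solves the Rayleigh secular cubic in the squared
#' ratio `eta = (c_R / c_s)^2`:
#' `eta^3 - 8 eta^2 + 8 (3 - 2 xi) eta - 16 (1 - xi) = 0`, with
#' `xi = (1 - 2 nu) / (2 (1 - nu))`, taking the root in (0, 1) to 1e-12;
#' at nu = 0.5 this gives 0.9553 (the Rayleigh wave travels at ~95.5% of the
#' shear speed in an incompressible medium). `"approximate"` uses the
#' classical Viktorov form `(0.87 + 1.12 nu) / (1 + nu)`.
#'
#' @param nu Poisson's ratio in `[0, 0.5]`.
#' @param method `"exact_secular"` (default) or `"approximate"`.
#' @return The dimensionless speed ratio in (0, 1).
#' @export
rayleigh_shear_ratio <- function(nu = 0.5, method = c("exact_secular", "approximate")) {
  method <- match.arg(method)
  if (nu < 0 || nu > 0.5) stop("nu must lie in [0, 0.5]")
  if (method == "approximate") return((0.87 + 1.12 * nu) / (1 + nu))
  xi <- (1 - 2 * nu) / (2 * (1 - nu))
  f <- function(eta) eta^3 - 8 * eta^2 + 8 * (3 - 2 * xi) * eta - 16 * (1 - xi)
  if (f(1e-12) * f(1 - 1e-12) > 0)
    stop("no secular root in (0, 1); invalid Poisson's ratio?")
  eta <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  sqrt(eta)
}

#' Convert a Rayleigh-wave group velocity to a shear-wave speed
#'
#' Divides the measured surface wave speed by [rayleigh_shear_ratio()],
#' putting surface-wave (OCE) measurements on the shear-wave scale for
#' direct comparison with ultrasound elastography.
#'
#' @param Cg Measured Rayleigh/surface group velocity (m/s, > 0).
#' @param nu Poisson's ratio in `[0, 0.5]`.
#' @param method Ratio method, see [rayleigh_shear_ratio()].
#' @return Equivalent shear wave speed (m/s).
#' @export
rayleigh_to_shear_speed <- function(Cg, nu = 0.5, method = "exact_secular") {
  if (!is.finite(Cg) || Cg <= 0) stop("Cg must be positive")
  Cg / rayleigh_shear_ratio(nu, method)
}

#' @export
print.elasticity_result <- function(x, ...) {
  cat(sprintf("Young's modulus: %.3f kPa (%s model, c = %.3f m/s)\n",
              x$young_modulus / 1000, x$model, x$input_speed))
  invisible(x)
}
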