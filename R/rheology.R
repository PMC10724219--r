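#' Carreau blood rheology parameters
#'
#' Container for the Carreau shear-thinning constitutive model of whole
#' blood plus its density. Defaults are the parameter set commonly used for
#' human blood in cerebrovascular modelling: zero-shear viscosity 0.056,
#' infinite-shear viscosity 0.0035 (both kg m^-1 s^-1, i.e. Pa s), time
#' constant 3.313 s, power-law index 0.3568, density 1060 kg m^-3.
#'
#' @param mu_zero Zero-shear viscosity (kg m^-1 s^-1).
#' @param mu_inf Infinite-shear viscosity (kg m^-1 s^-1); must be below
#'   `mu_zero`.
#' @param lambda_c Carreau time constant (s).
#' @param n_index Power-law index (dimensionless, in (0, 1] for
#'   shear-thinning behaviour).
#' @param rho Blood density (kg m^-3).
#' @return An object of class `rheology_params`.
#' @examples
#' p <- rheology_params()
#' carreau_viscosity(100, p)
#' @export
rheology_params <- function(mu_zero = 0.056, mu_inf = 0.0035,
                            lambda_c = 3.313, n_index = 0.3568,
                            rho = 1060) {
  stopifnot(is.numeric(mu_zero), is.numeric(mu_inf), is.numeric(lambda_c),
            is.numeric(n_index), is.numeric(rho))
  if (!(mu_inf > 0 && mu_zero > mu_inf))
    stop("rheology_params: need 0 < mu_inf < mu_zero", call. = FALSE)
  if (lambda_c <= 0) stop("rheology_params: lambda_c must be > 0", call. = FALSE)
  if (rho <= 0) stop("rheology_params: rho must be > 0", call. = FALSE)
  if (n_index <= 0 || n_index > 1)
    stop("rheology_params: n_index must lie in (0, 1]", call. = FALSE)
  structure(list(mu_zero = mu_zero, mu_inf = mu_inf, lambda_c = lambda_c,
                 n_index = n_index, rho = rho),
            class = "rheology_params")
}

#' @export
print.rheology_params <- function(x, ...) {
  cat("Carreau rheology: mu0 =", x$mu_zero, "mu_inf =", x$mu_inf,
      "lambda =", x$lambda_c, "s, n =", x$n_index,
      ", rho =", x$rho, "kg m^-3\n")
  invisible(x)
}

#' Straight conduit segment
#'
#' A rigid cylindrical vessel segment, the building block of the arterial
#' tree.
#'
#' @param name Segment identifier (e.g. `"ICA"`).
#' @param length Segment length (m), > 0.
#' @param radius Luminal radius (m), > 0.
#' @return An object of class `conduit`.
#' @export
conduit <- function(name, length, radius) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(length) || length <= 0)
    stop("conduit '", name, "': length must be > 0", call. = FALSE)
  if (!is.numeric(radius) || radius <= 0)
    stop("conduit '", name, "': radius must be > 0", call. = FALSE)
  structure(list(name = name, length = length, radius = radius),
            class = "conduit")
}

#' Carreau apparent viscosity
#'
#' Evaluates the Carreau model
#' \deqn{\mu(\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)\,[1 + (\lambda\gamma)^2]^{(n-1)/2}}
#' which interpolates monotonically between the zero-shear viscosity at
#' rest and the infinite-shear viscosity at high shear rates.
#'
#' @param gamma Shear rate (s^-1), >= 0. Vectorised.
#' @param params A [rheology_params()] object.
#' @return Apparent viscosity (kg m^-1 s^-1), always within
#'   `[mu_inf, mu_zero]`.
#' @export
carreau_viscosity <- function(gamma, params = rheology_params()) {
  if (any(!is.finite(gamma)) || any(gamma < 0))
    stop("carreau_viscosity: gamma must be finite and >= 0", call. = FALSE)
  params$mu_inf + (params$mu_zero - params$mu_inf) *
    (1 + (params$lambda_c * gamma)^2)^((params$n_index - 1) / 2)
}

#' Poiseuille wall shear rate
#'
#' Representative shear rate for a conduit carrying flow `Q`: the wall
#' shear rate of the parabolic (Poiseuille) profile, `4|Q| / (pi r^3)`.
#' This is the standard lumped-model closure coupling a shear-dependent
#' viscosity to a one-dimensional flow.
#'
#' @param flow Volumetric flow (m^3 s^-1). Vectorised.
#' @param radius Luminal radius (m), > 0.
#' @return Shear rate (s^-1), >= 0.
#' @export
poiseuille_wall_shear_rate <- function(flow, radius) {
  if (any(radius <= 0))
    stop("poiseuille_wall_shear_rate: radius must be > 0", call. = FALSE)
  4 * abs(flow) / (pi * radius^3)
}

#' Poiseuille resistance of a conduit
#'
#' Hydraulic resistance of fully developed laminar flow in a rigid
#' cylinder, `R = 8 mu L / (pi r^4)`.
#'
#' @param viscosity Dynamic viscosity (kg m^-1 s^-1), > 0.
#' @param conduit A [conduit()] object.
#' @return Resistance (kg m^-4 s^-1).
#' @export
poiseuille_resistance <- function(viscosity, conduit) {
  if (any(viscosity <= 0))
    stop("poiseuille_resistance: viscosity must be > 0", call. = FALSE)
  8 * viscosity * conduit$length / (pi * conduit$radius^4)
}

#' Pressure drop across a resistance
#'
#' `delta P = R Q`; the sign follows the flow.
#'
#' @param resistance Hydraulic resistance (kg m^-4 s^-1).
#' @param flow Volumetric flow (m^3 s^-1).
#' @return Pressure drop (Pa).
#' @export
pressure_drop <- function(resistance, flow) resistance * flow

#' Flow-dependent conduit resistance under Carreau rheology
#'
#' Solves the fixed point `R = 8 mu(gamma(Q)) L / (pi r^4)` with
#' `gamma = 4|Q|/(pi r^3)`. Because the Poiseuille wall shear rate depends
#' on the flow alone (not on the viscosity), the fixed point closes in a
#' single evaluation; the iteration is retained as a guard for alternative
#' shear-rate closures.
#'
#' @param flow Volumetric flow (m^3 s^-1).
#' @param conduit A [conduit()] object.
#' @param params A [rheology_params()] object.
#' @param tol Relative convergence tolerance on successive resistances.
#' @param max_iter Iteration cap.
#' @return Resistance (kg m^-4 s^-1).
#' @export
effective_segment_resistance <- function(flow, conduit,
                                         params = rheology_params(),
                                         tol = 1e-10, max_iter = 50L) {
  gamma <- poiseuille_wall_shear_rate(flow, conduit$radius)
  R <- poiseuille_resistance(carreau_viscosity(gamma, params), conduit)
  for (i in seq_len(max_iter)) {
    R_new <- poiseuille_resistance(carreau_viscosity(gamma, params), conduit)
    if (abs(R_new - R) <= tol * abs(R_new)) return(R_new)
    R <- R_new
  }
  stop("effective_segment_resistance: no convergence after ", max_iter,
       " iterations; last iterate ", R, call. = FALSE)
}
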