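#' Diffusion context for Brownian particle-size estimates
#'
#' Physical constants for Stokes-Einstein calculations in aqueous medium:
#' temperature (default 298.15 K), dynamic viscosity of water at 25 C
#' (default 8.9e-4 Pa s), and the exact SI Boltzmann constant.
#'
#' @param temperature absolute temperature (K).
#' @param viscosity dynamic viscosity (Pa s).
#' @return List of class `diffusion_context`.
#' @export
diffusion_context <- function(temperature = 298.15, viscosity = 8.9e-4) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (viscosity <= 0) stop("viscosity must be > 0")
  structure(list(temperature = temperature, viscosity = viscosity,
                 kB = 1.380649e-23),
            class = "diffusion_context")
}

#' Stokes-Einstein diffusion coefficient
#'
#' D = kB * T / (6 * pi * eta * r) for a spherical particle of radius `r`
#' in a fluid of viscosity `eta` at temperature `T`.
#'
#' @param r particle radius (m), > 0.
#' @param ctx a [diffusion_context()].
#' @return Diffusion coefficient (m^2/s).
#' @export
#' @examples
#' stokes_einstein_D(1.5e-9)  # ~1.6e-10 m^2/s
stokes_einstein_D <- function(r, ctx = diffusion_context()) {
  if (any(r <= 0)) stop("radius must be > 0")
  ctx$kB * ctx$temperature / (6 * pi * ctx$viscosity * r)
}

#' Mean three-dimensional Brownian traversal time
#'
#' From the mean-square displacement law L^2 = 6 D t: the time for a
#' particle with diffusion coefficient `D` to cover a root-mean-square
#' distance `L` is t = L^2 / (6 D).
#'
#' @param L distance (m), > 0.
#' @param D diffusion coefficient (m^2/s), > 0.
#' @return Time (s).
#' @export
traversal_time <- function(L, D) {
  if (any(L <= 0)) stop("distance L must be > 0")
  if (any(D <= 0)) stop("diffusion coefficient D must be > 0")
  L^2 / (6 * D)
}

#' Stokes-Einstein radius-bound prefactor
#'
#' The constant kB * T / (pi * eta) multiplying t / L^2 in the particle
#' radius bound; about 1.5e-18 m^2/s for water at 298.15 K.
#'
#' @param ctx a [diffusion_context()].
#' @return Prefactor (m^2/s).
#' @export
prefactor <- function(ctx = diffusion_context()) {
  ctx$kB * ctx$temperature / (pi * ctx$viscosity)
}

#' Upper bound on the radius of a diffusing signaling particle
#'
#' Combining L^2 = 6 D t with the Stokes-Einstein relation gives the
#' largest particle radius that can traverse a distance `L` within a time
#' `t` by free Brownian diffusion:
#' r = kB * T * t / (pi * eta * L^2) = [prefactor()] * t / L^2.
#'
#' Note: evaluated at the distance at which two hyphae enter dialogue
#' (L = 10 um) and a traversal-time budget of t = 10 s, this formula gives
#' r ~ 1.5e-7 m, whereas the bound quoted alongside the published formula
#' is ~1.5 nm -- a hundredfold discrepancy between the printed formula and
#' the printed end value that this function does not attempt to reconcile
#' (the result is returned as the formula states it; see the package
#' vignette).
#'
#' @param L distance (m), > 0.
#' @param t available traversal time (s), >= 0.
#' @param ctx a [diffusion_context()].
#' @return Radius bound (m).
#' @export
radius_upper_bound <- function(L, t, ctx = diffusion_context()) {
  if (any(L <= 0)) stop("distance L must be > 0")
  if (any(t < 0)) stop("time t must be >= 0")
  prefactor(ctx) * t / L^2
}
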