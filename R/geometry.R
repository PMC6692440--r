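#' Rectangular microchannel geometry
#'
#' Describes the duct through which the solution flows. The default matches
#' the square PDMS microchannel used to emulate inter-bundle gaps in
#' myocardial tissue: 50 x 50 um cross-section, 15 mm long.
#'
#' @param width Channel width `w` in metres (the direction the velocity
#'   profile is measured across). Must be positive.
#' @param height Channel height `h` in metres. Must be positive.
#' @param length Channel length `L` in metres. Must be positive.
#'
#' @return An object of class `channel_geometry` with fields `width`,
#'   `height`, `length`.
#' @examples
#' geom <- channel_geometry()
#' geom$width
#' @export
channel_geometry <- function(width = 50e-6, height = 50e-6, length = 15e-3) {
  stopifnot(is.numeric(width), length(width) == 1L, is.finite(width),
            is.numeric(height), length(height) == 1L, is.finite(height),
            is.numeric(length), length(length) == 1L, is.finite(length))
  if (width <= 0 || height <= 0 || length <= 0)
    stop("channel dimensions must be strictly positive", call. = FALSE)
  structure(list(width = width, height = height, length = length),
            class = "channel_geometry")
}

#' Power-law (Ostwald-de Waele) fluid with wall slip
#'
#' Viscosity model mu = K * gammadot^(n-1). `n = 1` is Newtonian, `n < 1`
#' shear-thinning, `n > 1` shear-thickening. The wall-slip velocity `u0` is a
#' constant Dirichlet value imposed at the channel walls, the usual idealized
#' treatment of the apparent slip of polymer solutions in microchannels.
#'
#' @param density Mass density rho in kg m^-3 (default 1200, a 10% m/v
#'   polyethylene-glycol solution).
#' @param K Consistency index in Pa s^n (equals the viscosity at a shear rate
#'   of 1 s^-1). Must be positive.
#' @param n Power-law index (dimensionless), in (0, 2].
#' @param u0 Wall-slip velocity in m s^-1, >= 0.
#'
#' @return An object of class `power_law_fluid`.
#' @examples
#' fl <- power_law_fluid(K = 1.0, n = 0.883, u0 = 0)
#' @export
power_law_fluid <- function(density = 1200, K = 1.0, n = 0.883, u0 = 0) {
  stopifnot(is.numeric(density), is.numeric(K), is.numeric(n), is.numeric(u0),
            length(density) == 1L, length(K) == 1L, length(n) == 1L,
            length(u0) == 1L)
  if (!is.finite(density) || density <= 0)
    stop("density must be positive", call. = FALSE)
  if (!is.finite(K) || K <= 0)
    stop("consistency index K must be positive", call. = FALSE)
  if (!is.finite(n) || n <= 0 || n > 2)
    stop("invalid fluid: power-law index n must lie in (0, 2]", call. = FALSE)
  if (!is.finite(u0) || u0 < 0)
    stop("slip velocity u0 must be >= 0", call. = FALSE)
  structure(list(density = density, K = K, n = n, u0 = u0),
            class = "power_law_fluid")
}

#' Apparent viscosity of a power-law fluid
#'
#' @param fluid A [power_law_fluid()].
#' @param gammadot Shear-rate magnitude(s) in s^-1.
#' @param floor Regularization floor in s^-1 applied to `gammadot` before
#'   exponentiation, avoiding the singularity of `K * gammadot^(n-1)` at zero
#'   shear for `n < 1`.
#' @return Viscosities in Pa s.
#' @export
apparent_viscosity <- function(fluid, gammadot, floor = 0) {
  stopifnot(inherits(fluid, "power_law_fluid"))
  fluid$K * pmax(gammadot, floor)^(fluid$n - 1)
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> w = %g um, h = %g um, L = %g mm\n",
              x$width * 1e6, x$height * 1e6, x$length * 1e3))
  invisible(x)
}

#' @export
print.power_law_fluid <- function(x, ...) {
  cat(sprintf(
    "<power_law_fluid> rho = %g kg/m^3, K = %g Pa.s^n, n = %g, u0 = %g m/s\n",
    x$density, x$K, x$n, x$u0))
  invisible(x)
}
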