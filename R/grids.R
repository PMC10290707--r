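#' Spectral grid for refractive-index construction and reported IOPs
#'
#' The model constructs refractive indices on a wide input grid and reports
#' inherent optical properties (IOPs) on a narrower output grid strictly
#' inside it, so that edge effects of the discrete Hilbert transform never
#' reach the reported range.
#'
#' @param range_in numeric length 2, input wavelength range in nm
#'   (default 380--900).
#' @param range_out numeric length 2, output (reported) range in nm
#'   (default 400--850); must lie strictly inside `range_in`.
#' @return An object of class `spectral_grid` with integer wavelength vectors
#'   `wl_in` and `wl_out` (1 nm step) and the index `idx_out` of the output
#'   wavelengths within the input grid.
#' @examples
#' g <- spectral_grid()
#' length(g$wl_out)  # 451
#' @export
spectral_grid <- function(range_in = c(380, 900), range_out = c(400, 850)) {
  stopifnot(length(range_in) == 2, length(range_out) == 2)
  if (!(range_out[1] > range_in[1] && range_out[2] < range_in[2]))
    stop("output range must lie strictly inside the input range")
  wl_in <- seq(range_in[1], range_in[2], by = 1)
  wl_out <- seq(range_out[1], range_out[2], by = 1)
  structure(list(
    wl_in = wl_in,
    wl_out = wl_out,
    idx_out = match(wl_out, wl_in)
  ), class = "spectral_grid")
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> input %d-%d nm, output %d-%d nm, 1 nm step\n",
              min(x$wl_in), max(x$wl_in), min(x$wl_out), max(x$wl_out)))
  invisible(x)
}

#' Angular grid for scattering functions
#'
#' Uniform midpoint grid of scattering angles on (0, 180) degrees.  The
#' default 1800 samples sit at 0.05, 0.15, ..., 179.95 degrees; avoiding the
#' exact forward direction keeps the quadrature of the strongly forward-peaked
#' intensity well behaved.  Quadrature weights are composite-midpoint weights
#' including the `sin(theta)` Jacobian, in radians.
#'
#' @param n number of angular samples (default 1800).
#' @return Object of class `angular_grid` with fields `theta_deg`,
#'   `theta_rad`, `mu` (`cos(theta)`), `w` (quadrature weights
#'   `sin(theta) * dtheta`), and logical `back` marking the backward
#'   hemisphere (theta > 90 degrees).
#' @examples
#' ag <- angular_grid()
#' sum(ag$w)  # ~ 2 == integral of sin(theta) over (0, pi)
#' @export
angular_grid <- function(n = 1800) {
  stopifnot(n >= 2)
  theta_deg <- (seq_len(n) - 0.5) * 180 / n
  theta_rad <- theta_deg * pi / 180
  structure(list(
    theta_deg = theta_deg,
    theta_rad = theta_rad,
    mu = cos(theta_rad),
    w = sin(theta_rad) * pi / n,
    back = theta_deg > 90
  ), class = "angular_grid")
}

#' @export
print.angular_grid <- function(x, ...) {
  n <- length(x$theta_deg)
  cat(sprintf("<angular_grid> %d samples, %.3f..%.3f deg\n",
              n, x$theta_deg[1], x$theta_deg[n]))
  invisible(x)
}

as_angular_grid <- function(x) {
  if (inherits(x, "angular_grid")) return(x)
  if (is.numeric(x) && length(x) == 1) return(angular_grid(x))
  stop("expected an angular_grid or a sample count")
}
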