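#' Cell morphology parameters
#'
#' Bundles the biophysical parameters of the two-layer cell model: the
#' relative volume of the pigmented shell (chloroplast in eukaryotes,
#' chromatoplasm in vacuolate cyanobacteria), the intracellular chlorophyll-a
#' density of the whole cell, and the unpackaged chlorophyll-a-specific
#' absorption at 675 nm used to anchor the imaginary refractive index.
#'
#' @param c_i intracellular Chl-a density, kg m-3 (whole cell); healthy
#'   cultures span roughly 0.5--8.
#' @param V_v relative shell volume fraction, in (0, 1); default 0.2.
#' @param a_sol_675 Chl-a-specific absorption of unpackaged (in-solution)
#'   pigment at 675 nm, m2 mg-1; default 0.027.
#' @return Object of class `cell_morphology` with fields `c_i`, `V_v`,
#'   `V_c = 1 - V_v`, `a_sol_675`.
#' @export
cell_morphology <- function(c_i, V_v = 0.2, a_sol_675 = 0.027) {
  if (!is.numeric(c_i) || length(c_i) != 1 || !is.finite(c_i) || c_i <= 0)
    stop("parameter error: c_i must be a positive scalar (kg m-3)")
  if (!(V_v > 0 && V_v < 1))
    stop("parameter error: V_v must lie strictly between 0 and 1")
  if (a_sol_675 <= 0)
    stop("parameter error: a_sol_675 must be positive")
  structure(list(c_i = c_i, V_v = V_v, V_c = 1 - V_v,
                 a_sol_675 = a_sol_675),
            class = "cell_morphology")
}

#' Complex refractive index of a particle layer
#'
#' Wavelength-indexed complex refractive index relative to the medium,
#' `m = n - i n'`, for one layer of the coated sphere (or a homogenised
#' equivalent).  The imaginary part `n'` is non-negative; the sign convention
#' of the time factor is handled internally by the scattering kernel.
#'
#' @param layer one of `"core"`, `"shell"`, `"homogenized"`.
#' @param grid a [spectral_grid()].
#' @param n real part, numeric vector on `grid$wl_in` (relative to medium).
#' @param n_prime imaginary part, numeric vector on `grid$wl_in`, `>= 0`.
#' @param n_media real refractive index of the medium (default 1.334).
#' @return Object of class `complex_ri`.
#' @export
complex_ri <- function(layer = c("core", "shell", "homogenized"),
                       grid, n, n_prime, n_media = 1.334) {
  layer <- match.arg(layer)
  stopifnot(inherits(grid, "spectral_grid"))
  nw <- length(grid$wl_in)
  if (length(n) != nw || length(n_prime) != nw)
    stop("n and n_prime must be defined on the full input grid")
  if (any(!is.finite(n)) || any(!is.finite(n_prime)))
    stop("propagation error: non-finite refractive index values")
  if (any(n <= 0)) stop("real refractive index must be positive everywhere")
  if (any(n_prime < 0))
    stop("imaginary refractive index must be non-negative everywhere")
  structure(list(layer = layer, wl = grid$wl_in, n = n, n_prime = n_prime,
                 n_media = n_media),
            class = "complex_ri")
}

#' @export
print.complex_ri <- function(x, ...) {
  cat(sprintf(
    "<complex_ri> %s layer, %d-%d nm; n in [%.4f, %.4f], n' in [%.2e, %.2e]\n",
    x$layer, min(x$wl), max(x$wl), min(x$n), max(x$n),
    min(x$n_prime), max(x$n_prime)))
  invisible(x)
}

ri_at <- function(ri, wavelength) {
  i <- match(wavelength, ri$wl)
  if (any(is.na(i))) stop("wavelength not on the refractive-index grid")
  list(n = ri$n[i], n_prime = ri$n_prime[i])
}

#' Scale a pigment absorption shape to the shell imaginary refractive index
#'
#' The spectral shape of in-vivo pigment absorption carries no absolute
#' magnitude; it is anchored at 675 nm, where chlorophyll a dominates and the
#' cytoplasm core is assumed non-absorbing.  The anchor equates the shell
#' material absorption at 675 nm with the unpackaged pigment absorption of
#' the chlorophyll concentrated into the shell, `a = (c_i / V_v) * a_sol`,
#' through the standard relation `n' = a * lambda_medium / (4 pi)`.
#'
#' @param shape non-negative spectrum on `grid$wl_in` (arbitrary units);
#'   must be positive at 675 nm.
#' @param morph a [cell_morphology()].
#' @param grid a [spectral_grid()].
#' @param n_media medium refractive index (default 1.334).
#' @return The shell imaginary refractive index spectrum (dimensionless),
#'   equal to `shape` times a single scalar.
#' @examples
#' g <- spectral_grid()
#' shp <- exp(-((g$wl_in - 675) / 15)^2)
#' np <- scale_imaginary_ri(shp, cell_morphology(c_i = 2), g)
#' np[g$wl_in == 675]  # ~ 0.01087
#' @export
scale_imaginary_ri <- function(shape, morph, grid, n_media = 1.334) {
  stopifnot(inherits(morph, "cell_morphology"),
            inherits(grid, "spectral_grid"))
  if (length(shape) != length(grid$wl_in))
    stop("shape must be defined on the full input grid")
  if (any(!is.finite(shape)) || any(shape < 0))
    stop("invalid-shape error: shape must be finite and non-negative")
  i675 <- match(675, grid$wl_in)
  if (is.na(i675)) stop("input grid must contain 675 nm")
  if (shape[i675] <= 0)
    stop("invalid-shape error: shape must be positive at 675 nm")
  c_i_mg <- morph$c_i * 1e6                      # kg m-3 -> mg m-3
  a675 <- (c_i_mg / morph$V_v) * morph$a_sol_675 # m-1, shell material
  lambda_med <- 675e-9 / n_media                 # m
  target <- a675 * lambda_med / (4 * pi)
  shape * (target / shape[i675])
}

#' Discrete Hilbert transform (conjugate dispersion shape)
#'
#' Computes the harmonic conjugate of a spectrum sampled on a uniform grid
#' using the half-sample discrete Hilbert kernel `2 / (pi (i - j))` over
#' index offsets of odd parity, which is spectrally accurate for smooth,
#' well-resolved bands.  A linear trend through the two endpoints is removed
#' first so that signals without band structure (in particular constants)
#' transform to exactly zero instead of picking up window artefacts.
#'
#' @param y numeric vector on a uniform grid.
#' @return Numeric vector: the conjugate (dispersion) shape, with the
#'   convention that an absorption band produces a dispersion curve that is
#'   negative on the short-wavelength side of the band and positive on the
#'   long-wavelength side.
#' @export
hilbert_dispersion <- function(y) {
  if (any(!is.finite(y))) stop("propagation error: non-finite input")
  n <- length(y)
  idx <- seq_len(n)
  tr <- y[1] + (y[n] - y[1]) * (idx - 1) / (n - 1)
  z <- y - tr
  out <- numeric(n)
  for (i in idx) {
    k <- idx[(idx - i) %% 2L != 0L]
    out[i] <- (2 / pi) * sum(z[k] / (i - k))
  }
  out
}

#' Derive the real refractive index shape from the imaginary part
#'
#' The real part of the refractive index is obtained as the Kramers-Kronig
#' (Hilbert) conjugate of the imaginary part: the discrete Hilbert transform
#' supplies the dispersion shape around each absorption band, and a constant
#' offset anchors the spectral mean over the output range to a prescribed
#' magnitude taken from the literature (1.10 for the chloroplast shell,
#' 1.02 for the cytoplasm core).
#'
#' @param n_prime imaginary refractive index on `grid$wl_in`.
#' @param magnitude target spectral mean of `n` over the output range.
#' @param grid a [spectral_grid()].
#' @return The real refractive index spectrum on `grid$wl_in`.
#' @export
derive_real_ri <- function(n_prime, magnitude, grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  if (length(n_prime) != length(grid$wl_in))
    stop("n_prime must be defined on the full input grid")
  if (any(!is.finite(n_prime)))
    stop("propagation error: non-finite values in n_prime")
  disp <- hilbert_dispersion(n_prime)
  disp - mean(disp[grid$idx_out]) + magnitude
}

#' Shell (chloroplast) complex refractive index from a pigment shape
#'
#' Convenience constructor chaining [scale_imaginary_ri()] and
#' [derive_real_ri()].
#'
#' @inheritParams scale_imaginary_ri
#' @param magnitude spectral-mean anchor of the real part (default 1.10).
#' @return A [complex_ri()] for the shell layer.
#' @export
build_shell_ri <- function(shape, morph, grid, magnitude = 1.10,
                           n_media = 1.334) {
  np <- scale_imaginary_ri(shape, morph, grid, n_media)
  n <- derive_real_ri(np, magnitude, grid)
  complex_ri("shell", grid, n, np, n_media)
}

#' Core (cytoplasm) complex refractive index
#'
#' The cytoplasm is modelled as a weakly absorbing, mostly aqueous medium
#' whose imaginary refractive index decays exponentially with wavelength,
#' `n'(lambda) = amp400 * exp(-slope * (lambda - 400))`; the real part is the
#' Hilbert conjugate anchored to a spectral mean of 1.02.
#'
#' @param grid a [spectral_grid()].
#' @param amp400 imaginary RI at 400 nm (default 1e-4); must be `>= 0`.
#' @param slope spectral decay rate, nm-1 (default 0.01); must be `>= 0`.
#' @param magnitude real-part anchor (default 1.02).
#' @param n_media medium refractive index.
#' @return A [complex_ri()] for the core layer.
#' @export
build_core_ri <- function(grid, amp400 = 1e-4, slope = 0.01,
                          magnitude = 1.02, n_media = 1.334) {
  stopifnot(inherits(grid, "spectral_grid"))
  if (amp400 < 0) stop("parameter error: amp400 must be non-negative")
  if (slope < 0) stop("parameter error: slope must be non-negative")
  np <- amp400 * exp(-slope * (grid$wl_in - 400))
  n <- derive_real_ri(np, magnitude, grid)
  complex_ri("core", grid, n, np, n_media)
}

#' Vacuole core refractive index (prokaryote variant)
#'
#' In the gas-vacuolate cyanobacterial variant the core sphere represents a
#' vacuole-like inclusion of low refractive index instead of cytoplasm.  The
#' default values are configurable stand-ins for a gas-filled inclusion
#' (relative real RI below 1, negligible absorption); they are not derived
#' from measurements.
#'
#' @param grid a [spectral_grid()].
#' @param core_real_ri flat relative real RI of the vacuole (default 0.75).
#' @param core_imag_ri flat imaginary RI (default 1e-9).
#' @param n_media medium refractive index.
#' @return A [complex_ri()] for the core layer.
#' @export
vacuole_core_ri <- function(grid, core_real_ri = 0.75, core_imag_ri = 1e-9,
                            n_media = 1.334) {
  stopifnot(inherits(grid, "spectral_grid"))
  if (core_imag_ri < 0) stop("parameter error: core_imag_ri must be >= 0")
  nw <- length(grid$wl_in)
  complex_ri("core", grid, rep(core_real_ri, nw), rep(core_imag_ri, nw),
             n_media)
}

#' Gladstone-Dale homogenisation of the two-layer refractive indices
#'
#' Volume-weighted linear mixing of the core and shell complex refractive
#' indices into the equivalent homogeneous particle:
#' `n_hom = n_core V_c + n_shell V_s` and likewise for the imaginary part.
#' The model bases no scattering calculation on the homogenised particle; it
#' is provided for comparison with whole-cell refractive indices reported in
#' the literature and to parameterise the carbon term.
#'
#' @param core,shell [complex_ri()] objects on the same grid.
#' @param V_c,V_s core and shell volume fractions; must sum to 1 within 1e-12.
#' @return A [complex_ri()] with `layer = "homogenized"`.
#' @export
gladstone_dale <- function(core, shell, V_c, V_s) {
  stopifnot(inherits(core, "complex_ri"), inherits(shell, "complex_ri"))
  if (!isTRUE(all.equal(V_c + V_s, 1, tolerance = 1e-12)))
    stop("parameter error: V_c + V_s must equal 1")
  if (!identical(core$wl, shell$wl))
    stop("core and shell must share a wavelength grid")
  g <- structure(list(wl_in = core$wl,
                      wl_out = core$wl, idx_out = seq_along(core$wl)),
                 class = "spectral_grid")
  complex_ri("homogenized", g,
             core$n * V_c + shell$n * V_s,
             core$n_prime * V_c + shell$n_prime * V_s,
             core$n_media)
}

#' Intracellular carbon density from the real refractive index
#'
#' Empirical linear relation between intracellular carbon density and the
#' whole-cell real refractive index at 660 nm:
#' `C_i = 3441.055 * n(660) - 3404.99` (kg m-3).  Values of `n660` below
#' about 0.9895 give negative carbon and indicate an out-of-domain input.
#'
#' @param n660 real refractive index (relative) at 660 nm.
#' @return Intracellular carbon density, kg m-3.
#' @export
carbon_from_real_ri <- function(n660) {
  stopifnot(is.numeric(n660), all(is.finite(n660)))
  3441.055 * n660 - 3404.99
}

#' Intracellular chlorophyll density from the imaginary refractive index
#'
#' Empirical linear relation `c_i = 996.86 * n'(675) - 1.17` (kg m-3).
#' Whether the density refers to the pigmented compartment or the whole cell
#' is an ambiguity of the source relation (the two differ by the shell volume
#' fraction); no correction is applied here.
#'
#' @param n_prime_675 imaginary refractive index at 675 nm.
#' @return Intracellular Chl-a density, kg m-3.
#' @export
chl_from_imag_ri <- function(n_prime_675) {
  stopifnot(is.numeric(n_prime_675), all(is.finite(n_prime_675)))
  996.86 * n_prime_675 - 1.17
}

#' Linear-slope edge extrapolation of a spectral shape
#'
#' Measured pigment-absorption shapes are reliable on roughly 385--800 nm;
#' beyond that range the shape is extended by the straight line fitted to the
#' outermost `fit_span` nm of trusted data (clamped at zero), which keeps the
#' Hilbert transform free of step artefacts at the grid edges.
#'
#' @param shape spectrum on `grid$wl_in`.
#' @param grid a [spectral_grid()].
#' @param trusted numeric length 2: wavelength range of trusted values
#'   (default `c(385, 800)`).
#' @param fit_span nm of trusted data used for each edge slope (default 10).
#' @return The shape with both edges replaced by slope extrapolations.
#' @export
extrapolate_edges <- function(shape, grid, trusted = c(385, 800),
                              fit_span = 10) {
  stopifnot(inherits(grid, "spectral_grid"))
  wl <- grid$wl_in
  out <- shape
  lo <- trusted[1]; hi <- trusted[2]
  fit_lo <- wl >= lo & wl <= lo + fit_span
  sl <- stats::coef(stats::lm(shape[fit_lo] ~ wl[fit_lo]))
  left <- wl < lo
  out[left] <- pmax(0, sl[1] + sl[2] * wl[left])
  fit_hi <- wl >= hi - fit_span & wl <= hi
  sh <- stats::coef(stats::lm(shape[fit_hi] ~ wl[fit_hi]))
  right <- wl > hi
  out[right] <- pmax(0, sh[1] + sh[2] * wl[right])
  out
}
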