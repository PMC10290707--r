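#' Particle geometry for the coated-sphere kernel
#'
#' Converts a physical outer diameter and core volume fraction into the
#' dimensionless size parameters used by the scattering engine,
#' `x = pi d n_media / lambda` with the vacuum wavelength (equivalently the
#' in-medium wavenumber times the radius); refractive indices are relative to
#' the medium throughout.
#'
#' @param d_outer outer diameter, micrometres.
#' @param core_fraction core-to-outer volume ratio `V_c`, in `[0, 1]`;
#'   the core diameter is `d_outer * core_fraction^(1/3)`.
#' @param lambda vacuum wavelength, nm.
#' @param n_media medium real refractive index (default 1.334).
#' @return Object of class `particle_geometry` with diameters (um), the
#'   wavelength and the size parameters `x_core`, `x_shell`.
#' @export
particle_geometry <- function(d_outer, core_fraction, lambda,
                              n_media = 1.334) {
  stopifnot(d_outer > 0, core_fraction >= 0, core_fraction <= 1, lambda > 0)
  d_core <- d_outer * core_fraction^(1 / 3)
  lam_um <- lambda / 1000
  x_shell <- pi * d_outer * n_media / lam_um
  x_core <- pi * d_core * n_media / lam_um
  structure(list(d_outer = d_outer, d_core = d_core,
                 core_fraction = core_fraction, lambda = lambda,
                 n_media = n_media, x_core = x_core, x_shell = x_shell),
            class = "particle_geometry")
}

default_nmax_cap <- function() {
  getOption("phytoiop.nmax_cap", 6000L)
}

make_particle_optics <- function(res, grid, area_m2 = NA_real_) {
  Qb <- res$Qsca
  Qa <- res$Qabs
  po <- list(Qext = res$Qext, Qb = Qb, Qa = Qa,
             nterms = res$nterms, area_m2 = area_m2,
             sigma_a = Qa * area_m2, sigma_b = Qb * area_m2)
  if (!is.null(res$S11)) {
    po$S11 <- res$S11
    bs <- backscatter_from_angular(res$S11, grid, Qb)
    po$Qbb <- bs$Qbb
    po$bb_prob <- bs$bb_prob
    po$sigma_bb <- bs$Qbb * area_m2
    if (is.finite(area_m2) && po$sigma_b > 0) {
      pv <- phase_and_vsf(res$S11, grid, po$sigma_b)
      po$phase <- pv$phase
      po$vsf_kernel <- pv$vsf_kernel
    }
    po$angles <- grid
  }
  structure(po, class = "particle_optics")
}

#' @export
print.particle_optics <- function(x, ...) {
  cat(sprintf("<particle_optics> Qext=%.4g Qb=%.4g Qa=%.4g%s (N=%d)\n",
              x$Qext, x$Qb, x$Qa,
              if (!is.null(x$Qbb)) sprintf(" Qbb=%.4g", x$Qbb) else "",
              x$nterms))
  invisible(x)
}

#' Homogeneous-sphere Mie scattering
#'
#' Standard Mie series for a homogeneous sphere, truncated at
#' `N = ceiling(x + 4.05 x^(1/3) + 2)` terms.  Serves as the degenerate limit
#' and cross-check of the stratified (coated) engine.
#'
#' @param x size parameter (`pi d n_media / lambda`), `> 0`.
#' @param m complex refractive index relative to the medium; the imaginary
#'   part may be given with either sign convention.
#' @param angles an [angular_grid()] (or sample count), or `NULL` to skip
#'   angular quantities.
#' @param area_m2 optional geometric cross-section (m2) used to populate
#'   absorption/scattering cross-sections.
#' @param nmax_cap explicit cap on the series length; exceeding it is an
#'   error, never a silent truncation.
#' @return A `particle_optics` object with efficiencies `Qext`, `Qa`, `Qb`,
#'   and, when `angles` is supplied, the unpolarised angular intensity `S11`,
#'   backscattering efficiency `Qbb`, backscatter probability and phase
#'   function.
#' @export
mie_homogeneous <- function(x, m, angles = angular_grid(), area_m2 = NA_real_,
                            nmax_cap = default_nmax_cap()) {
  stopifnot(is.numeric(x), length(x) == 1, x > 0)
  m <- as.complex(m)
  ag <- if (is.null(angles)) NULL else as_angular_grid(angles)
  res <- mie_single_cpp(0, x, m, m,
                        if (is.null(ag)) numeric(0) else ag$mu,
                        TRUE, as.integer(nmax_cap))
  make_particle_optics(res, ag, area_m2)
}

#' Coated-sphere (stratified two-layer) scattering
#'
#' Computes scattering and absorption by a concentric two-layer sphere with
#' given core and shell complex refractive indices, using a numerically
#' stable effective-logarithmic-derivative recursion tolerant of absorbing
#' layers at size parameters of several hundred.
#'
#' @param geom a [particle_geometry()].
#' @param m_core,m_shell complex refractive indices relative to the medium
#'   (scalars, `m = n - i n'` or `n + i n'`).
#' @param angles an [angular_grid()] (or count), or `NULL` for efficiencies
#'   only.
#' @param nmax_cap series-length cap (see [mie_homogeneous()]).
#' @return A `particle_optics` object; cross-sections use the geometric
#'   cross-section of the outer sphere.
#' @export
coated_sphere_scattering <- function(geom, m_core, m_shell,
                                     angles = angular_grid(),
                                     nmax_cap = default_nmax_cap()) {
  stopifnot(inherits(geom, "particle_geometry"))
  ag <- if (is.null(angles)) NULL else as_angular_grid(angles)
  area <- pi * (geom$d_outer * 1e-6)^2 / 4
  res <- mie_single_cpp(geom$x_core, geom$x_shell,
                        as.complex(m_core), as.complex(m_shell),
                        if (is.null(ag)) numeric(0) else ag$mu,
                        FALSE, as.integer(nmax_cap))
  make_particle_optics(res, ag, area)
}

#' Backscatter probability and efficiency from the angular intensity
#'
#' The backscatter probability is the fraction of scattered energy directed
#' into the backward hemisphere,
#' `b_prob = int_{90}^{180} S11 sin(theta) dtheta / int_0^180 S11 sin(theta)
#' dtheta`, evaluated with the grid's composite-midpoint weights; the
#' backscattering efficiency is `Qbb = b_prob * Qb`.
#'
#' @param S11 non-negative angular intensity on `grid`.
#' @param grid an [angular_grid()].
#' @param Qb scattering efficiency of the same particle.
#' @return List with `Qbb` and `bb_prob`.
#' @export
backscatter_from_angular <- function(S11, grid, Qb) {
  grid <- as_angular_grid(grid)
  if (length(S11) != length(grid$mu))
    stop("S11 must be sampled on the angular grid")
  if (any(S11 < 0)) stop("S11 must be non-negative")
  tot <- sum(grid$w * S11)
  if (tot <= 0) stop("undefined-probability error: S11 is identically zero")
  bb_prob <- sum(grid$w[grid$back] * S11[grid$back]) / tot
  list(Qbb = bb_prob * Qb, bb_prob = bb_prob)
}

#' Phase function and per-particle VSF kernel
#'
#' Normalises the angular intensity to a phase function with
#' `2 pi int phase(theta) sin(theta) dtheta = 1` (units sr-1) and forms the
#' per-particle volume-scattering-function kernel `phase * sigma_b`
#' (m2 sr-1), whose solid-angle integral returns the scattering
#' cross-section.
#'
#' @param S11 angular intensity on `grid`.
#' @param grid an [angular_grid()].
#' @param sigma_b scattering cross-section, m2, `> 0`.
#' @return List with `phase` (sr-1) and `vsf_kernel` (m2 sr-1).
#' @export
phase_and_vsf <- function(S11, grid, sigma_b) {
  grid <- as_angular_grid(grid)
  if (!(sigma_b > 0)) stop("sigma_b must be positive")
  if (length(S11) != length(grid$mu))
    stop("S11 must be sampled on the angular grid")
  tot <- 2 * pi * sum(grid$w * S11)
  if (tot <= 0) stop("phase-function normalization integral is not positive")
  phase <- S11 / tot
  list(phase = phase, vsf_kernel = phase * sigma_b)
}
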