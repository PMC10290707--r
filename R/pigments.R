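#' Gaussian pigment absorption band
#'
#' @param center band centre, nm.
#' @param width Gaussian standard deviation, nm, `> 0`.
#' @param height relative amplitude, `>= 0`.
#' @return Object of class `pigment_band`.
#' @export
pigment_band <- function(center, width, height) {
  if (!(width > 0)) stop("band width must be positive")
  if (height < 0) stop("band height must be non-negative")
  structure(list(center = center, width = width, height = height),
            class = "pigment_band")
}

#' Synthetic in-vivo pigment absorption shape from Gaussian bands
#'
#' Builds a smooth stand-in for a measured mean in-vivo Chl-a-specific
#' absorption shape as a sum of Gaussian pigment bands over a flat baseline:
#' `shape(lambda) = baseline + sum(height * exp(-(lambda-center)^2 /
#' (2 width^2)))`.  Packaged presets (see [pg_pigment_presets()]) approximate
#' the diagnostic pigment complements of the library groups; they are
#' deterministic constructions, not measurements.
#'
#' @param bands list of [pigment_band()] objects.
#' @param grid a [spectral_grid()].
#' @param baseline flat relative offset (default 0.005).
#' @return Non-negative shape spectrum on `grid$wl_in` (arbitrary units).
#' @export
synth_pigment_absorption <- function(bands, grid, baseline = 0.005) {
  stopifnot(inherits(grid, "spectral_grid"))
  if (length(bands) == 0 && baseline <= 0)
    stop("degenerate-shape error: no bands and zero baseline")
  wl <- grid$wl_in
  shape <- rep(baseline, length(wl))
  for (b in bands) {
    stopifnot(inherits(b, "pigment_band"))
    shape <- shape + b$height * exp(-(wl - b$center)^2 / (2 * b$width^2))
  }
  shape
}

band_set <- function(...) {
  spec <- list(...)
  lapply(spec, function(v) pigment_band(v[1], v[2], v[3]))
}

# shared chlorophyll-a bands (Soret + red peak)
chl_a_bands <- function(red_height = 0.65) {
  band_set(c(438, 24, 1.00), c(675, 11, red_height))
}

#' Synthetic pigment-band presets for the 17 library groups
#'
#' Returns, for each phytoplankton group of the packaged library, a list of
#' Gaussian bands approximating its diagnostic accessory pigments (e.g. a
#' 620 nm phycocyanin band for blue-mode cyanobacteria, a ~565 nm
#' phycoerythrin band for red-mode cyanobacteria and Synechococcus, Chl b
#' bands for green algae, broad fucoxanthin/carotenoid shoulders for diatoms
#' and dinoflagellates).  These are documented stand-ins chosen for spectral
#' diversity, not fits to culture measurements.
#'
#' @return Named list (one element per group) of lists of [pigment_band()].
#' @export
pg_pigment_presets <- function() {
  fuco <- c(500, 28, 0.45)        # fucoxanthin shoulder
  carot <- c(470, 20, 0.45)       # beta-carotene / xanthophyll shoulder
  chl_b <- list(c(480, 16, 0.40), c(650, 12, 0.25))
  chl_c <- c(635, 10, 0.12)
  peri <- c(540, 25, 0.35)        # peridinin
  pc <- c(620, 16, 0.45)          # phycocyanin
  pe <- c(565, 18, 0.45)          # phycoerythbilin
  allo <- c(490, 18, 0.35)        # alloxanthin
  zea <- c(455, 18, 0.40)         # zeaxanthin
  g <- list(
    "Diatoms (pennate)" = band_set(fuco, chl_c),
    "Chlorophytes" = c(band_set(chl_b[[1]]), band_set(chl_b[[2]])),
    "Diatoms (centric)" = band_set(fuco, carot, chl_c, c(530, 15, 0.18)),
    "Cryptophytes" = band_set(allo, pe, chl_c),
    "Cyanobacteria blue" = band_set(pc, zea),
    "Cyanobacteria red" = band_set(pe, zea),
    "Dinoflagellates" = band_set(fuco, peri, chl_c),
    "Eustigmatophytes" = band_set(carot, c(495, 18, 0.30)),
    "Haptophytes: Pavlovaceae" = band_set(fuco, chl_c, c(460, 14, 0.25)),
    "Pelagophytes" = band_set(fuco, chl_c),
    "Prasinophytes" = c(band_set(chl_b[[1]]), band_set(chl_b[[2]],
                                                       c(455, 14, 0.2))),
    "Prochlorococcus" = band_set(zea, c(442, 16, 0.5)),
    "Haptophytes: Prymnesiaceae" = band_set(fuco, c(467, 16, 0.30), chl_c),
    "Raphidophytes" = band_set(fuco, carot, chl_c),
    "Rhodophytes" = band_set(pe, c(498, 16, 0.25), zea),
    "Synechococcus" = band_set(pe, zea),
    "Microcystis" = band_set(pc, zea)
  )
  lapply(g, function(bands) c(chl_a_bands(), bands))
}

#' Synthetic mean imaginary-RI shapes for all packaged groups
#'
#' Evaluates the packaged Gaussian-band presets on the input grid, giving one
#' mean-shape spectrum per group in the same layout as a mean in-vivo
#' absorption library file.
#'
#' @param grid a [spectral_grid()].
#' @param baseline flat offset passed to [synth_pigment_absorption()].
#' @return Named list of shape spectra on `grid$wl_in`.
#' @export
synthetic_invivo_means <- function(grid = spectral_grid(), baseline = 0.005) {
  lapply(pg_pigment_presets(), synth_pigment_absorption, grid = grid,
         baseline = baseline)
}

#' Read a mean in-vivo imaginary-RI library file
#'
#' Reads the documented CSV layout: first column `wavelength` spanning
#' 380--900 nm at 1 nm, then one column per phytoplankton group holding the
#' mean imaginary refractive index shape.  Values outside 385--800 nm are
#' edge extrapolations supplied only to stabilise the Hilbert transform; the
#' returned shapes carry an `extrapolated` attribute marking that range.
#'
#' @param path CSV file path.
#' @param grid a [spectral_grid()]; the file grid must match `grid$wl_in`.
#' @return Named list of shape spectra (one per group column).
#' @export
read_invivo_means <- function(path, grid = spectral_grid()) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2)
    stop("format error: need a wavelength column plus at least one group")
  wl <- df[[1]]
  if (!isTRUE(all.equal(as.numeric(wl), as.numeric(grid$wl_in))))
    stop("format error: wavelength grid must be ",
         min(grid$wl_in), "-", max(grid$wl_in), " nm at 1 nm")
  shapes <- lapply(df[-1], as.numeric)
  for (nm in names(shapes)) {
    v <- shapes[[nm]]
    if (any(!is.finite(v))) stop("data error: non-finite values in ", nm)
    if (any(v < 0)) stop("data error: negative values in ", nm)
    attr(shapes[[nm]], "extrapolated") <- grid$wl_in < 385 | grid$wl_in > 800
  }
  shapes
}

#' @rdname read_invivo_means
#' @param shapes named list of shape spectra on `grid$wl_in`.
#' @export
write_invivo_means <- function(shapes, path, grid = spectral_grid()) {
  stopifnot(length(shapes) >= 1, !is.null(names(shapes)))
  df <- c(list(wavelength = sprintf("%d", grid$wl_in)),
          lapply(shapes, function(v) {
            stopifnot(length(v) == length(grid$wl_in))
            sprintf("%.17g", v)
          }))
  df <- as.data.frame(df, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
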