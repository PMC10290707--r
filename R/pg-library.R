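#' Phytoplankton-group specifications of the packaged library
#'
#' The parameter grid of the packaged spectral library: 16 eukaryote groups
#' plus one vacuolate prokaryote, each with a set of assemblage effective
#' diameters spanning its natural size range and intracellular Chl-a
#' densities of 2, 5 and 8 kg m-3.
#'
#' @return Data frame with columns `name` (group label), `file` (output file
#'   stem), `d_eff` (list column, micrometres), `c_i` (list column, kg m-3),
#'   `prokaryote` (logical) and `pigments` (comment string).
#' @export
pg_groups <- function() {
  ci <- list(c(2, 5, 8))
  df <- data.frame(
    name = c("Diatoms (pennate)", "Chlorophytes", "Diatoms (centric)",
             "Cryptophytes", "Cyanobacteria blue", "Cyanobacteria red",
             "Dinoflagellates", "Eustigmatophytes",
             "Haptophytes: Pavlovaceae", "Pelagophytes", "Prasinophytes",
             "Prochlorococcus", "Haptophytes: Prymnesiaceae",
             "Raphidophytes", "Rhodophytes", "Synechococcus", "Microcystis"),
    file = c("Diatoms_Pennate", "Chlorophytes", "Diatoms_Centric",
             "Cryptophytes", "Cyano_blue", "Cyano_red", "Dinoflagellates",
             "Eustigmatophytes", "Haptophytes_Pavlovaceae", "Pelagophytes",
             "Prasinophytes", "Prochlorococcus", "Haptophytes_Prymnesiaceae",
             "Raphidophytes", "Rhodophytes", "Synechococcus", "Microcystis"),
    prokaryote = c(rep(FALSE, 16), TRUE),
    stringsAsFactors = FALSE
  )
  df$d_eff <- list(
    c(6, 12, 24, 48), c(2, 4, 6, 8), c(6, 12, 24, 48), c(2, 6, 12, 24, 48),
    c(2, 6, 12, 24), c(2, 6, 12, 24), c(2, 6, 12, 24), c(2, 6, 12, 24),
    c(2, 6, 12, 24), c(1, 2, 3, 4), c(2, 3, 4, 5), c(0.4, 0.5, 0.7, 0.9),
    c(1, 2, 3, 4), c(12, 24, 48, 60), c(2, 6, 12, 24, 48),
    c(0.4, 0.8, 1.2, 1.8), c(3, 4, 5, 6))
  df$c_i <- rep(ci, 17)
  df$pigments <- c(
    "fucoxanthin, Chl c, beta-carotene", "Chl b, violaxanthin",
    "fucoxanthin, photoprotective carotenoids", "alloxanthin, phycobilins",
    "phycocyanin", "phycoerythrin", "fucoxanthin, peridinin",
    "beta-carotene, violaxanthin", "Chl c1/c2",
    "fucoxanthin", "Chl b, prasinoxanthin", "divinyl pigments, zeaxanthin",
    "19'-acyloxyfucoxanthins", "Chl c, fucoxanthin",
    "phycobilins, alpha-carotene", "phycoerythrin",
    "phycocyanin (vacuolate)")
  df
}

#' Vacuole configuration for the prokaryote variant
#'
#' Collects the stand-in parameters of the gas-vacuole core: its flat
#' relative refractive index, negligible absorption, and the vacuole volume
#' fraction of the cell (the shell then carries thylakoids plus cytoplasm).
#' Values are configurable defaults, not measurements; the library's use of
#' them is qualitative (elevated scattering), not quantitative.
#'
#' @param core_real_ri relative real RI of the vacuole core (default 0.75).
#' @param core_imag_ri imaginary RI of the core (default 1e-9), `>= 0`.
#' @param core_fraction vacuole volume fraction of the cell (default 0.15,
#'   within the documented range of gas-vesicle volume fractions).
#' @return Object of class `vacuole_config`.
#' @export
vacuole_config <- function(core_real_ri = 0.75, core_imag_ri = 1e-9,
                           core_fraction = 0.15) {
  if (core_imag_ri < 0) stop("core_imag_ri must be non-negative")
  stopifnot(core_real_ri > 0, core_fraction > 0, core_fraction < 1)
  structure(list(core_real_ri = core_real_ri, core_imag_ri = core_imag_ri,
                 core_fraction = core_fraction), class = "vacuole_config")
}

resolve_group <- function(group, specs = pg_groups()) {
  i <- match(group, specs$name)
  if (is.na(i)) i <- match(group, specs$file)
  if (is.na(i))
    stop("unknown group '", group, "'; valid names: ",
         paste(specs$name, collapse = ", "))
  specs[i, ]
}

#' Simulate the IOPs of one phytoplankton group assemblage
#'
#' End-to-end driver: builds the shell refractive index from the group's
#' pigment shape and `c_i`, the core (cytoplasm or vacuole) refractive index,
#' a standard size distribution normalised to 1 mg Chl m-3, and integrates
#' the coated-sphere optics over it.
#'
#' @param group group name (one of `pg_groups()$name` or `$file`).
#' @param c_i intracellular Chl-a density, kg m-3.
#' @param d_eff assemblage effective diameter, micrometres.
#' @param shape optional imaginary-RI shape on `grid$wl_in`; defaults to the
#'   packaged synthetic band preset for the group.
#' @param V_v shell volume fraction for eukaryotes (default 0.2).
#' @param v_eff effective variance of the size distribution (default 0.6).
#' @param n_bins diameter bins (default 50).
#' @param vacuole a [vacuole_config()] used when the group is prokaryote.
#' @param dist optional [size_distribution()] overriding the standard one
#'   (e.g. a measured distribution); it is Chl-normalised internally.
#' @param ... passed to [integrate_iops()] (`wavelengths`, `compute_vsf`,
#'   `angles`, `nmax_cap`, ...).
#' @param grid a [spectral_grid()].
#' @return An `assemblage_iops` object.
#' @export
simulate_group <- function(group, c_i, d_eff, shape = NULL, V_v = 0.2,
                           v_eff = 0.6, n_bins = 50,
                           vacuole = vacuole_config(), dist = NULL,
                           grid = spectral_grid(), ...) {
  spec <- resolve_group(group)
  if (is.null(shape)) {
    shape <- synth_pigment_absorption(pg_pigment_presets()[[spec$name]], grid)
  }
  if (spec$prokaryote) {
    # core = vacuole; pigmented shell fills the rest of the cell
    V_v <- 1 - vacuole$core_fraction
    core <- vacuole_core_ri(grid, vacuole$core_real_ri, vacuole$core_imag_ri)
  } else {
    core <- build_core_ri(grid)
  }
  morph <- cell_morphology(c_i = c_i, V_v = V_v)
  shell <- build_shell_ri(shape, morph, grid)
  if (is.null(dist)) dist <- make_standard_distribution(d_eff, v_eff, n_bins)
  dist <- chl_normalize(dist, c_i)
  integrate_iops(dist, morph, core, shell, grid = grid, ...)
}

iop_col_name <- function(iop, ci, deff) {
  sprintf("%s_Ci_%s_Deff_%s", iop, format(ci, trim = TRUE),
          format(deff, trim = TRUE))
}

#' Build the per-group IOP dataset on disk
#'
#' Batch driver regenerating the published dataset layout: one CSV per group
#' with a `wavelength` column (400--850 nm at 1 nm, 451 rows) and one column
#' per IOP (`a`, `b`, `bb`), intracellular Chl density and effective
#' diameter, named `"{iop}_Ci_{ci}_Deff_{deff}"` (units m2 mg-1).  Values are
#' written in scientific notation with 6 significant digits, so files
#' round-trip stably; the build is deterministic.  A `build_log.txt` with the
#' full configuration is written alongside the CSVs.
#'
#' @param out_dir output directory (created if missing).
#' @param specs group specification table as from [pg_groups()] (possibly a
#'   subset of rows).
#' @param shapes named list mapping group `name` to an imaginary-RI shape on
#'   the input grid; defaults to the synthetic band presets.  Entries missing
#'   from the list fall back to the presets.
#' @param V_v,v_eff,n_bins,vacuole,grid as in [simulate_group()];
#'   `n_bins` defaults to 50 (production quality; reduce for quick builds).
#' @param nmax_cap Mie series cap.
#' @param verbose print per-group progress.
#' @return Invisibly, the vector of files written.
#' @export
build_pg_dataset <- function(out_dir, specs = pg_groups(), shapes = NULL,
                             V_v = 0.2, v_eff = 0.6, n_bins = 50,
                             vacuole = vacuole_config(),
                             grid = spectral_grid(),
                             nmax_cap = default_nmax_cap(),
                             verbose = FALSE) {
  if (nrow(specs) == 0) {
    warning("empty specification list: nothing to build")
    return(invisible(character(0)))
  }
  if (anyDuplicated(specs$name))
    stop("name collision in group specifications")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  presets <- pg_pigment_presets()
  files <- character(0)
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    shape <- if (!is.null(shapes) && spec$name %in% names(shapes)) {
      shapes[[spec$name]]
    } else {
      synth_pigment_absorption(presets[[spec$name]], grid)
    }
    cols <- list(wavelength = sprintf("%d", grid$wl_out))
    for (ci in spec$c_i[[1]]) {
      for (deff in spec$d_eff[[1]]) {
        if (verbose)
          message(sprintf("%s: c_i=%g, D_eff=%g", spec$name, ci, deff))
        iops <- simulate_group(spec$name, c_i = ci, d_eff = deff,
                               shape = shape, V_v = V_v, v_eff = v_eff,
                               n_bins = n_bins, vacuole = vacuole,
                               grid = grid, compute_vsf = FALSE,
                               nmax_cap = nmax_cap)
        vals <- list(a = iops$a_star, b = iops$b_star, bb = iops$bb_star)
        for (iop in names(vals)) {
          nm <- iop_col_name(iop, ci, deff)
          if (nm %in% names(cols)) stop("name collision in columns: ", nm)
          cols[[nm]] <- formatC(vals[[iop]], format = "e", digits = 5)
        }
      }
    }
    path <- file.path(out_dir, paste0(spec$file, ".csv"))
    df <- as.data.frame(cols, check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    files <- c(files, path)
  }
  log <- c(
    sprintf("phytoiop %s dataset build", as.character(packageVersion("phytoiop"))),
    sprintf("groups: %s", paste(specs$name, collapse = "; ")),
    sprintf("V_v=%g v_eff=%g n_bins=%d nmax_cap=%d", V_v, v_eff, n_bins,
            as.integer(nmax_cap)),
    sprintf("vacuole: core_real_ri=%g core_imag_ri=%g core_fraction=%g",
            vacuole$core_real_ri, vacuole$core_imag_ri,
            vacuole$core_fraction),
    sprintf("grid: input %d-%d nm, output %d-%d nm",
            min(grid$wl_in), max(grid$wl_in),
            min(grid$wl_out), max(grid$wl_out)),
    sprintf("shapes: %s",
            if (is.null(shapes)) "synthetic band presets"
            else "user-supplied"))
  writeLines(log, file.path(out_dir, "build_log.txt"))
  invisible(files)
}

#' Export a discretised phase-function table
#'
#' Writes the assemblage phase function as a plain (angle x wavelength) CSV
#' for use as radiative-transfer input.  The format is documented (first
#' column `angle_deg`, one column per wavelength named `wl_<nm>`, values in
#' sr-1); no particular radiative-transfer code dialect is guaranteed.
#'
#' @param iops an `assemblage_iops` computed with `compute_vsf = TRUE`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_phase_table <- function(iops, path) {
  stopifnot(inherits(iops, "assemblage_iops"))
  if (is.null(iops$phase))
    stop("phase functions unavailable: recompute with compute_vsf = TRUE")
  df <- c(list(angle_deg = sprintf("%.2f", iops$angles$theta_deg)),
          setNames(lapply(seq_along(iops$wavelengths), function(j)
            formatC(iops$phase[j, ], format = "e", digits = 5)),
            sprintf("wl_%g", iops$wavelengths)))
  write.csv(as.data.frame(df, check.names = FALSE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
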