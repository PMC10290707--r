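test_that("synthetic pigment shapes follow the band construction", {
  g <- spectral_grid()
  flat <- synth_pigment_absorption(list(), g, baseline = 0.3)
  expect_equal(flat, rep(0.3, length(g$wl_in)))
  expect_error(synth_pigment_absorption(list(), g, baseline = 0),
               "degenerate-shape")

  one <- synth_pigment_absorption(list(pigment_band(675, 10, 1)), g,
                                  baseline = 0.001)
  expect_equal(g$wl_in[which.max(one)], 675)

  two <- synth_pigment_absorption(list(pigment_band(500, 20, 0.5),
                                       pigment_band(500, 20, 0.5)), g,
                                  baseline = 0.1)
  expect_equal(two - 0.1, 2 * (one_band <- synth_pigment_absorption(
    list(pigment_band(500, 20, 0.5)), g, baseline = 0) ), tolerance = 1e-14)
})

test_that("the packaged group table matches the published library layout", {
  pg <- pg_groups()
  expect_identical(nrow(pg), 17L)
  expect_false(anyDuplicated(pg$name) > 0)
  expect_identical(sum(pg$prokaryote), 1L)
  expect_identical(pg$name[pg$prokaryote], "Microcystis")
  expect_true(all(vapply(pg$d_eff, function(v) all(diff(v) > 0), logical(1))))
  expect_true(all(vapply(pg$c_i, function(v) identical(v, c(2, 5, 8)),
                         logical(1))))
  expect_setequal(pg$file, c(
    "Chlorophytes", "Cryptophytes", "Cyano_blue", "Cyano_red",
    "Diatoms_Centric", "Diatoms_Pennate", "Dinoflagellates",
    "Eustigmatophytes", "Haptophytes_Pavlovaceae",
    "Haptophytes_Prymnesiaceae", "Microcystis", "Pelagophytes",
    "Prasinophytes", "Prochlorococcus", "Raphidophytes", "Rhodophytes",
    "Synechococcus"))
  presets <- pg_pigment_presets()
  expect_setequal(names(presets), pg$name)
  # every preset resolves to a valid positive shape with a 675 anchor
  g <- spectral_grid()
  for (nm in names(presets)) {
    shp <- synth_pigment_absorption(presets[[nm]], g)
    expect_true(all(shp >= 0))
    expect_gt(shp[g$wl_in == 675], 0)
  }
})

test_that("mean-shape library files validate and round-trip exactly", {
  g <- spectral_grid()
  shapes <- synthetic_invivo_means(g)[c("Dinoflagellates", "Synechococcus")]
  path <- tempfile(fileext = ".csv")
  write_invivo_means(shapes, path, g)
  back <- read_invivo_means(path, g)
  expect_length(back, 2)
  expect_identical(as.numeric(back$Dinoflagellates),
                   as.numeric(shapes$Dinoflagellates))
  ex <- attr(back$Dinoflagellates, "extrapolated")
  expect_identical(sum(ex), sum(g$wl_in < 385 | g$wl_in > 800))

  # a file with a missing wavelength row fails grid validation
  lines <- readLines(path)
  writeLines(lines[-100], path)
  expect_error(read_invivo_means(path, g), "format error")

  # negative values are rejected
  shapes$Dinoflagellates[5] <- -1e-6
  write_invivo_means(shapes, path, g)
  expect_error(read_invivo_means(path, g), "data error")
  unlink(path)
})

test_that("dataset files obey the published column grammar", {
  pg <- pg_groups()[c(2, 17), ]      # one eukaryote, the prokaryote
  pg$d_eff <- list(c(2, 4), c(3, 4))
  pg$c_i <- list(2, 2)
  out <- tempfile("pgset")
  files <- build_pg_dataset(out, specs = pg, n_bins = 4)
  expect_length(files, 2)
  expect_true(all(file.exists(files)))
  for (f in files) {
    df <- read.csv(f, check.names = FALSE)
    expect_identical(nrow(df), 451L)
    expect_identical(df$wavelength, 400:850)
    cols <- setdiff(names(df), "wavelength")
    expect_length(cols, 3 * 1 * 2)  # iops x c_i x D_eff
    expect_true(all(grepl("^(a|b|bb)_Ci_[0-9.]+_Deff_[0-9.]+$", cols)))
    expect_true(all(vapply(df[cols], is.numeric, logical(1))))
    expect_true(all(as.matrix(df[cols]) >= 0))
  }
  # deterministic rebuild is byte-identical
  out2 <- tempfile("pgset2")
  files2 <- build_pg_dataset(out2, specs = pg, n_bins = 4)
  for (i in seq_along(files)) {
    expect_identical(readLines(files[i]), readLines(files2[i]))
  }
  expect_true(file.exists(file.path(out, "build_log.txt")))
  unlink(c(out, out2), recursive = TRUE)
})

test_that("an empty specification list warns and writes nothing", {
  out <- tempfile("pgempty")
  expect_warning(files <- build_pg_dataset(out, specs = pg_groups()[0, ]),
                 "empty")
  expect_length(files, 0)
})

test_that("vacuole core elevates scattering relative to the eukaryote model", {
  g <- spectral_grid()
  shp <- synth_pigment_absorption(pg_pigment_presets()[["Microcystis"]], g)
  vac <- vacuole_config()
  for (De in c(3, 6)) {
    dist0 <- make_standard_distribution(De, 0.6, 20)
    pro <- simulate_group("Microcystis", c_i = 2, d_eff = De, shape = shp,
                          n_bins = 20, vacuole = vac,
                          wavelengths = 550, compute_vsf = FALSE)
    euk <- {
      morph <- cell_morphology(2, V_v = 0.2)
      integrate_iops(chl_normalize(dist0, 2), morph, build_core_ri(g),
                     build_shell_ri(shp, morph, g), g,
                     wavelengths = 550, compute_vsf = FALSE)
    }
    expect_gt(pro$b_star, euk$b_star)
    expect_gt(pro$bb_star, euk$bb_star)
  }

  # with identical shell RI and geometry, the low-RI core elevates the
  # backward-hemisphere scattering
  morph <- cell_morphology(2, V_v = 1 - vac$core_fraction)
  shell <- build_shell_ri(shp, morph, g)
  dist <- chl_normalize(make_standard_distribution(5.1, 0.6, 20), 2)
  with_vac <- integrate_iops(dist, morph, vacuole_core_ri(g), shell, g,
                             wavelengths = 550, compute_vsf = FALSE)
  with_cyt <- integrate_iops(dist, morph, build_core_ri(g), shell, g,
                             wavelengths = 550, compute_vsf = FALSE)
  expect_gt(with_vac$bb_star, with_cyt$bb_star)
})

test_that("command-line interface runs and reports usage errors", {
  withr::with_tempdir({
    status <- run_cli(c("simulate", "--group", "Synechococcus",
                        "--ci", "2", "--deff", "1.2", "--bins", "4",
                        "--out", "out.csv"))
    expect_identical(status, 0L)
    df <- read.csv("out.csv")
    expect_identical(nrow(df), 451L)
    expect_named(df, c("wavelength", "a", "b", "bb"))

    expect_identical(run_cli(c("simulate", "--group", "NotAGroup",
                               "--ci", "2", "--deff", "1")), 1L)
    msgs <- capture.output(
      run_cli(c("simulate", "--group", "NotAGroup", "--ci", "2",
                "--deff", "1")), type = "message")
    expect_true(any(grepl("Synechococcus", msgs)))  # lists valid names

    expect_identical(run_cli(c("simulate", "--group", "Synechococcus")), 1L)
    expect_identical(run_cli(character(0)), 1L)
    expect_identical(run_cli(c("frobnicate")), 1L)
  })
})

test_that("built-in validation suite passes", {
  expect_identical(suppressMessages(run_cli("validate")), 0L)
})

test_that("phase-function export writes the documented table", {
  io <- simulate_group("Synechococcus", c_i = 2, d_eff = 1.2, n_bins = 5,
                       wavelengths = c(440, 550), compute_vsf = TRUE)
  path <- tempfile(fileext = ".csv")
  write_phase_table(io, path)
  df <- read.csv(path, check.names = FALSE)
  expect_identical(nrow(df), 1800L)
  expect_named(df, c("angle_deg", "wl_440", "wl_550"))
  unlink(path)
})
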