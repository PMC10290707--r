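test_that("homogeneous Mie reproduces the Rayleigh closed form", {
  x <- 0.01
  m <- 1.33 + 0i
  po <- mie_homogeneous(x, m, angles = NULL)
  q_ray <- 8 / 3 * x^4 * Mod((m^2 - 1) / (m^2 + 2))^2
  expect_lt(abs(po$Qb - q_ray) / q_ray, 1e-3)
})

test_that("non-absorbing spheres conserve energy exactly", {
  for (x in c(0.5, 5, 80)) {
    po <- mie_homogeneous(x, 1.05 + 0i, angles = NULL)
    expect_identical(po$Qa, 0)
    expect_identical(po$Qext, po$Qb)
  }
})

test_that("homogeneous Mie matches an independently coded series", {
  for (case in list(list(x = 5, m = 1.05 + 0.01i),
                    list(x = 20, m = 1.15 + 0.003i),
                    list(x = 0.8, m = 1.02 + 1e-4i))) {
    po <- mie_homogeneous(case$x, case$m, angles = NULL)
    or <- oracle_homogeneous(case$x, case$m)
    expect_lt(abs(po$Qext - or$Qext) / or$Qext, 1e-8)
    expect_lt(abs(po$Qb - or$Qsca) / or$Qsca, 1e-8)
  }
})

test_that("series truncation is converged at the default length", {
  for (x in c(5, 60)) {
    m <- 1.08 + 0.005i
    base <- oracle_homogeneous(x, m)
    more <- oracle_homogeneous(x, m, nmax = oracle_nmax(x) + 25)
    expect_lt(abs(base$Qext - more$Qext), 1e-10)
    po <- mie_homogeneous(x, m, angles = NULL)
    expect_lt(abs(po$Qext - more$Qext) / more$Qext, 1e-10)
  }
})

test_that("energy conservation holds across a randomized (x, m) sweep", {
  set.seed(42)
  for (i in 1:20) {
    x <- 10^runif(1, -2, log10(700))
    m_shell <- complex(real = runif(1, 1.01, 1.2),
                       imaginary = 10^runif(1, -5, -1.3))
    geom_f <- runif(1, 0.2, 0.95)
    po <- mie_single_cpp(x * geom_f^(1 / 3), x, 1.02 + 1e-6i, m_shell,
                         numeric(0), FALSE, 6000L)
    expect_lt(abs(po$Qext - (po$Qabs + po$Qsca)), 1e-6 * po$Qext)
    expect_gte(po$Qabs, 0)
    expect_gte(po$Qsca, 0)
  }
})

test_that("degenerate coated sphere equals the homogeneous solution", {
  set.seed(1)
  for (i in 1:12) {
    x <- 10^runif(1, -1, log10(700))
    m <- complex(real = runif(1, 1.01, 1.2),
                 imaginary = 10^runif(1, -5, -1.5))
    h <- mie_single_cpp(0, x, m, m, numeric(0), TRUE, 6000L)
    cc <- mie_single_cpp(x * runif(1, 0.2, 0.95)^(1 / 3), x, m, m,
                         numeric(0), FALSE, 6000L)
    expect_lt(abs(cc$Qext - h$Qext) / h$Qext, 1e-8)
    expect_lt(abs(cc$Qsca - h$Qsca) / h$Qsca, 1e-8)
  }
})

test_that("vanishing core converges to a homogeneous shell-material sphere", {
  m1 <- 1.02 + 1e-4i
  m2 <- 1.10 + 0.01i
  geom0 <- particle_geometry(2, 0, 675)
  h <- mie_homogeneous(geom0$x_shell, m2, angles = NULL)
  for (f in c(1e-6, 1e-9, 0)) {
    geom <- particle_geometry(2, f, 675)
    cc <- coated_sphere_scattering(geom, m1, m2, angles = NULL)
    expect_lt(abs(cc$Qext - h$Qext) / h$Qext, 1e-6)
  }
})

test_that("coated sphere matches the electrostatic limit and the
           boundary-condition solve oracle", {
  # Rayleigh regime: exact two-layer polarizability
  x2 <- 0.01
  f <- 0.8
  m1 <- 1.02 + 1e-4i
  m2 <- 1.10 + 0.01i
  po <- mie_single_cpp(x2 * f^(1 / 3), x2, m1, m2, numeric(0), FALSE, 6000L)
  alpha <- rayleigh_coated(f, m1, m2)
  expect_lt(abs(po$Qsca - 8 / 3 * x2^4 * Mod(alpha)^2) /
              (8 / 3 * x2^4 * Mod(alpha)^2), 1e-3)
  expect_lt(abs(po$Qabs - 4 * x2 * Im(alpha)) / (4 * x2 * Im(alpha)), 1e-3)

  # 6 um cell at 675 nm (x ~ 37): independent direct solve of the
  # interface conditions with explicit Bessel function values
  geom <- particle_geometry(6, 0.8, 675)
  m2b <- 1.10 + 0.0109i
  m1b <- 1.02 + 1e-6i
  po2 <- coated_sphere_scattering(geom, m1b, m2b, angles = NULL)
  or <- oracle_coated(geom$x_core, geom$x_shell, m1b, m2b)
  expect_lt(abs(po2$Qa - (or$Qext - or$Qsca)) / (or$Qext - or$Qsca), 1e-6)
  expect_lt(abs(po2$Qext - or$Qext) / or$Qext, 1e-8)

  # low-RI (vacuole-like) core
  or2 <- oracle_coated(12 * 0.15^(1 / 3), 12, 0.75 + 0i, 1.10 + 0.004i)
  po3 <- mie_single_cpp(12 * 0.15^(1 / 3), 12, 0.75 + 0i, 1.10 + 0.004i,
                        numeric(0), FALSE, 6000L)
  expect_lt(abs(po3$Qext - or2$Qext) / or2$Qext, 1e-8)
})

test_that("angular intensity agrees with an independent evaluation", {
  ag <- angular_grid(600)
  geom <- particle_geometry(3, 0.8, 550)
  m1 <- 1.02 + 1e-5i
  m2 <- 1.09 + 0.008i
  po <- coated_sphere_scattering(geom, m1, m2, angles = ag)
  or <- oracle_coated(geom$x_core, geom$x_shell, m1, m2)
  s11_or <- oracle_s11(or$a, or$b, ag$mu)
  expect_lt(max(abs(po$S11 - s11_or)) / max(s11_or), 1e-8)
})

test_that("series cap raises an explicit error instead of truncating", {
  expect_error(mie_homogeneous(900, 1.05 + 0i, angles = NULL, nmax_cap = 500),
               "cap")
  # raising the cap makes the same call succeed
  po <- mie_homogeneous(900, 1.05 + 0i, angles = NULL, nmax_cap = 2000)
  expect_true(is.finite(po$Qext))
})

test_that("backscatter probability behaves for canonical patterns", {
  ag <- angular_grid()
  iso <- rep(1, length(ag$mu))
  expect_equal(backscatter_from_angular(iso, ag, 1)$bb_prob, 0.5,
               tolerance = 1e-12)
  ray <- 1 + ag$mu^2  # fore-aft symmetric Rayleigh pattern
  expect_equal(backscatter_from_angular(ray, ag, 1)$bb_prob, 0.5,
               tolerance = 1e-12)
  expect_error(backscatter_from_angular(rep(0, length(ag$mu)), ag, 1),
               "undefined-probability")

  # strongly forward-peaked pattern of a large particle
  po <- mie_homogeneous(150, 1.05 + 0.001i, angles = ag)
  expect_lt(po$bb_prob, 0.05)
  # matches direct quadrature of the independently computed intensity
  or <- oracle_homogeneous(150, 1.05 + 0.001i)
  s11_or <- oracle_s11(or$a, or$b, ag$mu)
  bb_or <- sum(ag$w[ag$back] * s11_or[ag$back]) / sum(ag$w * s11_or)
  expect_equal(po$bb_prob, bb_or, tolerance = 1e-8)

  # halving the angular resolution barely moves bb_prob for smooth patterns
  ag2 <- angular_grid(900)
  po2 <- mie_homogeneous(20, 1.06 + 0.004i, angles = ag2)
  po1 <- mie_homogeneous(20, 1.06 + 0.004i, angles = angular_grid(1800))
  expect_lt(abs(po1$bb_prob - po2$bb_prob), 1e-4)
})

test_that("phase functions normalise to unit solid-angle integral", {
  ag <- angular_grid()
  iso <- rep(1, length(ag$mu))
  pv <- phase_and_vsf(iso, ag, sigma_b = 2e-12)
  expect_equal(pv$phase, rep(1 / (4 * pi), length(iso)), tolerance = 1e-6)
  expect_equal(2 * pi * sum(ag$w * pv$vsf_kernel), 2e-12, tolerance = 1e-15)

  po <- mie_homogeneous(30, 1.07 + 0.005i, angles = ag, area_m2 = 1e-11)
  expect_lt(abs(2 * pi * sum(ag$w * po$phase) - 1), 1e-4)
  expect_equal(2 * pi * sum(ag$w * po$vsf_kernel), po$sigma_b,
               tolerance = 1e-4)
  expect_error(phase_and_vsf(iso, ag, sigma_b = 0), "sigma_b")
})

test_that("coated efficiencies satisfy Qbb <= Qb and non-negativity", {
  set.seed(9)
  ag <- angular_grid(900)
  for (i in 1:6) {
    geom <- particle_geometry(runif(1, 0.5, 20), runif(1, 0.3, 0.9),
                              sample(450:700, 1))
    po <- coated_sphere_scattering(geom, 1.02 + 1e-5i,
                                   complex(real = runif(1, 1.04, 1.14),
                                           imaginary = 10^runif(1, -4, -1.7)),
                                   angles = ag)
    expect_gte(po$Qbb, 0)
    expect_lte(po$Qbb, po$Qb)
    expect_gte(po$bb_prob, 0)
    expect_lte(po$bb_prob, 1)
  }
})
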