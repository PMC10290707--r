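# Independent scattering oracles, deliberately coded along different routes
# than the package kernel: explicit spherical Bessel function values (Miller
# downward normalisation for complex argument, base-R half-integer Bessel for
# real argument) and a direct linear solve of the interface conditions.

# spherical Bessel j_0..j_nmax of complex argument by downward recurrence
sph_jn_all <- function(nmax, z) {
  ns <- nmax + 25 + ceiling(Mod(z))
  jj <- complex(ns + 2)
  jj[ns + 2] <- 0
  jj[ns + 1] <- 1e-280
  for (n in ns:1) jj[n] <- (2 * n + 1) / z * jj[n + 1] - jj[n + 2]
  jj[seq_len(nmax + 1)] * ((sin(z) / z) / jj[1])
}

sph_yn_all <- function(nmax, z) {
  yy <- complex(nmax + 1)
  yy[1] <- -cos(z) / z
  if (nmax >= 1) yy[2] <- (-cos(z) / z - sin(z)) / z
  if (nmax >= 2) for (n in 1:(nmax - 1))
    yy[n + 2] <- (2 * n + 1) / z * yy[n + 1] - yy[n]
  yy
}

# Riccati-Bessel values and derivatives for orders 1..nmax
ricatti <- function(nmax, z) {
  j <- sph_jn_all(nmax, z)
  y <- sph_yn_all(nmax, z)
  psi <- z * j
  chi <- -z * y
  n <- 1:nmax
  list(f = psi[n + 1],
       df = psi[n] - n / z * psi[n + 1],
       g = chi[n + 1],
       dg = chi[n] - n / z * chi[n + 1])
}

# real-argument Riccati-Bessel via base R half-integer Bessel functions
ricatti_real <- function(nmax, x) {
  n <- 1:nmax
  fac <- sqrt(pi * x / 2)
  psi <- fac * besselJ(x, n + 0.5)
  psi0 <- fac * besselJ(x, n - 0.5)
  chi <- -fac * besselY(x, n + 0.5)
  chi0 <- -fac * besselY(x, n - 0.5)
  list(f = psi, df = psi0 - n / x * psi,
       g = chi, dg = chi0 - n / x * chi)
}

oracle_nmax <- function(x) ceiling(x + 4.05 * x^(1 / 3) + 2)

# homogeneous Mie by the explicit cross-product formulas
oracle_homogeneous <- function(x, m, nmax = oracle_nmax(x)) {
  int <- ricatti(nmax, m * x)
  ext <- ricatti_real(nmax, x)
  xi <- ext$f - 1i * ext$g
  dxi <- ext$df - 1i * ext$dg
  a <- (m * int$f * ext$df - ext$f * int$df) /
       (m * int$f * dxi - xi * int$df)
  b <- (int$f * ext$df - m * ext$f * int$df) /
       (int$f * dxi - m * xi * int$df)
  n <- 1:nmax
  list(Qext = 2 / x^2 * sum((2 * n + 1) * Re(a + b)),
       Qsca = 2 / x^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2)),
       a = a, b = b)
}

solve_equilibrated <- function(A, rhs) {
  s <- apply(abs(A), 2, max)
  x <- solve(A %*% diag(1 / s), rhs)
  x / s
}

# coated sphere by direct solve of the interface conditions:
# TM: U and U'_rho/m continuous; TE: U/m and U'_rho continuous
oracle_coated <- function(x1, x2, m1, m2, nmax = oracle_nmax(x2)) {
  u <- ricatti(nmax, m1 * x1)
  s1 <- ricatti(nmax, m2 * x1)
  s2 <- ricatti(nmax, m2 * x2)
  ext <- ricatti_real(nmax, x2)
  a <- b <- complex(nmax)
  for (n in 1:nmax) {
    xi <- ext$f[n] - 1i * ext$g[n]
    dxi <- ext$df[n] - 1i * ext$dg[n]
    A <- matrix(c(
      u$f[n], -s1$f[n], -s1$g[n], 0,
      u$df[n] / m1, -s1$df[n] / m2, -s1$dg[n] / m2, 0,
      0, s2$f[n], s2$g[n], xi,
      0, s2$df[n] / m2, s2$dg[n] / m2, dxi), 4, 4, byrow = TRUE)
    a[n] <- solve_equilibrated(A, c(0, 0, ext$f[n], ext$df[n]))[4]
    B <- matrix(c(
      u$f[n] / m1, -s1$f[n] / m2, -s1$g[n] / m2, 0,
      u$df[n], -s1$df[n], -s1$dg[n], 0,
      0, s2$f[n] / m2, s2$g[n] / m2, xi,
      0, s2$df[n], s2$dg[n], dxi), 4, 4, byrow = TRUE)
    b[n] <- solve_equilibrated(B, c(0, 0, ext$f[n], ext$df[n]))[4]
  }
  n <- 1:nmax
  list(Qext = 2 / x2^2 * sum((2 * n + 1) * Re(a + b)),
       Qsca = 2 / x2^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2)),
       a = a, b = b)
}

# unpolarised angular intensity from expansion coefficients (plain R path)
oracle_s11 <- function(a, b, mu) {
  nmax <- length(a)
  S1 <- S2 <- complex(length(mu))
  pim1 <- rep(0, length(mu))
  pin <- rep(1, length(mu))
  for (n in 1:nmax) {
    tau <- n * mu * pin - (n + 1) * pim1
    f <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + f * (a[n] * pin + b[n] * tau)
    S2 <- S2 + f * (a[n] * tau + b[n] * pin)
    pinp <- ((2 * n + 1) * mu * pin - (n + 1) * pim1) / n
    pim1 <- pin
    pin <- pinp
  }
  (Mod(S1)^2 + Mod(S2)^2) / 2
}

# electrostatic (Rayleigh) polarizability of a coated sphere
rayleigh_coated <- function(f, m1, m2) {
  e1 <- m1^2
  e2 <- m2^2
  ((e2 - 1) * (e1 + 2 * e2) + f * (e1 - e2) * (1 + 2 * e2)) /
    ((e2 + 2) * (e1 + 2 * e2) + f * (e1 - e2) * (2 * e2 - 2))
}

# analytic Kramers-Kronig (Hilbert) pair: Lorentzian absorption band
lorentz_pair <- function(wl, center, gamma) {
  u <- gamma^2 / ((wl - center)^2 + gamma^2)
  v <- gamma * (wl - center) / ((wl - center)^2 + gamma^2)
  list(u = u, v = v)
}
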