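# Spectral machinery: wave speeds, Maxwell discriminant spectrum, Zener cubic
# roots (Cardano vs companion matrix), essential spectrum, equivalent time
# constants, attenuation formulae.

test_that("wave speeds follow the thin-wall scaling", {
  g <- validation_tube()
  m <- maxwell_from_speed(5, g, tau = 0.2)
  expect_equal(wave_speeds(m, g)$c, 5)
  # c ~ sqrt(e), c ~ 1/sqrt(rho)
  g2 <- tube_geometry(g$r, g$e / 4, g$L, g$rho)
  expect_equal(wave_speeds(m, g2)$c, 2.5)
  g3 <- tube_geometry(g$r, g$e, g$L, 2 * g$rho)
  expect_equal(wave_speeds(m, g3)$c, 5 / sqrt(2))

  z <- zener_from_speeds(4, 3, g, tau = 2)
  sp <- wave_speeds(z, g)
  expect_equal(c(sp$c0, sp$c1, sp$c), c(4, 3, 5))

  # E0 = 0 collapses to the Maxwell speed
  z0 <- zener_material(0, m$E1, 0.2)
  expect_equal(wave_speeds(z0, g)$c, 5)
})

test_that("PDMS conduit speed matches the fitted-card prediction", {
  expect_equal(wave_speeds(pdms_card(), carotid_tube())$c, 13.808,
               tolerance = 1e-4)
})

test_that("tube geometry rejects thick walls and warns near the limit", {
  expect_error(tube_geometry(r = 0.004, e = 0.0021, L = 1), "0.25")
  expect_warning(tube_geometry(r = 0.004, e = 0.0017, L = 1), "marginal")
})

test_that("Maxwell spectrum: discriminant regimes, mu11, ordering, k_critical", {
  g <- validation_tube()
  m <- maxwell_from_speed(5, g, tau = 0.2)
  sp <- maxwell_spectrum(m, g, n_max = 20)
  # printed dominant overdamped rate
  expect_equal(Re(sp$modes$rate1[1]), -0.555, tolerance = 5e-4)
  expect_equal(sp$k_critical, floor(10 / (2 * 5 * pi * 0.2)))
  over <- sp$modes$regime == "overdamped"
  expect_true(all(which(over) <= sp$k_critical))
  # ordering mu2 < -1/(2 tau) < mu1 < 0 for overdamped modes
  expect_true(all(Re(sp$modes$rate2[over]) < -1 / (2 * 0.2)))
  expect_true(all(Re(sp$modes$rate1[over]) > -1 / (2 * 0.2)))
  expect_true(all(Re(sp$modes$rate1[over]) < 0))
  # underdamped modes decay at exactly -1/(2 tau) with omega = sqrt(-Delta)
  under <- sp$modes$regime == "underdamped"
  expect_true(any(under))
  expect_equal(Re(sp$modes$rate1[under]), rep(-2.5, sum(under)))
  lam <- sp$modes$lambda_n[under]
  expect_equal(sp$modes$omega_n[under],
               sqrt(lam * 25 - 1 / (4 * 0.2^2)))
})

test_that("slow-relaxation Maxwell walls leave every mode underdamped", {
  g <- validation_tube()
  m <- maxwell_from_speed(5, g, tau = 2)
  sp <- maxwell_spectrum(m, g, n_max = 50)
  expect_equal(sp$k_critical, 0)
  expect_true(all(sp$modes$regime == "underdamped"))
})

test_that("huge viscosity limit gives pure oscillation at c sqrt(lambda_n)", {
  g <- validation_tube()
  m <- maxwell_from_speed(5, g, tau = 1e9)
  sp <- maxwell_spectrum(m, g, n_max = 5)
  expect_equal(sp$modes$omega_n, 5 * sqrt(sp$modes$lambda_n),
               tolerance = 1e-9)
  expect_true(all(abs(Re(sp$modes$rate1)) < 1e-8))
})

test_that("Maxwell tau_eq branches join continuously and match -1/mu11", {
  g <- validation_tube()
  # overdamped branch equals the reciprocal of the slowest rate
  m <- maxwell_from_speed(5, g, tau = 0.2)
  sp <- maxwell_spectrum(m, g, 1)
  expect_equal(maxwell_tau_eq(m, g), -1 / Re(sp$modes$rate1[1]),
               tolerance = 1e-12)
  # underdamped branch: 2 tau
  m2 <- maxwell_from_speed(5, g, tau = 2)
  expect_equal(maxwell_tau_eq(m2, g), 4)
  # boundary 4 tau^2 pi^2 c^2 / L^2 = 1: both branches give 2 tau
  tau_b <- 10 / (2 * pi * 5)
  mb <- maxwell_from_speed(5, g, tau = tau_b)
  expect_equal(maxwell_tau_eq(mb, g), 2 * tau_b, tolerance = 1e-9)
  mb2 <- maxwell_from_speed(5, g, tau = tau_b * (1 - 1e-9))
  expect_equal(maxwell_tau_eq(mb2, g), 2 * tau_b, tolerance = 1e-4)
})

test_that("Zener mode roots satisfy Vieta identities and positivity", {
  g <- validation_tube()
  z <- zener_from_speeds(4, 3, g, tau = 0.2)
  for (n in c(1, 3, 10)) {
    r <- zener_mode_roots(z, g, n)
    lam <- (n * pi / 10)^2
    expect_equal(Re(sum(r)), 1 / 0.2, tolerance = 1e-9)
    expect_equal(Re(r[1] * r[2] + r[1] * r[3] + r[2] * r[3]), lam * 25,
                 tolerance = 1e-9)
    expect_equal(Re(prod(r)), lam * 16 / 0.2, tolerance = 1e-9)
    expect_true(all(Re(r) >= 0))
  }
})

test_that("Cardano and companion-matrix roots agree over random draws", {
  set.seed(101)
  for (i in 1:1000) {
    tau <- runif(1, 0.01, 5)
    c0 <- runif(1, 0.1, 20)
    c1 <- runif(1, 0.1, 20)
    L <- runif(1, 0.5, 50)
    n <- sample(1:50, 1)
    lam <- (n * pi / L)^2
    # the constructor errors if the two disagree beyond 1e-9 relative
    r <- viscopulse:::zener_cubic_roots(tau, c0^2, c1^2, lam)
    expect_length(r, 3)
  }
})

test_that("Zener decay constants reproduce the validation-case values", {
  g <- validation_tube()
  z2 <- zener_from_speeds(4, 3, g, tau = 2)
  expect_equal(zener_decay_constant(z2, g, 1), 11.59, tolerance = 0.005)
  z02 <- zener_from_speeds(4, 3, g, tau = 0.2)
  expect_equal(zener_decay_constant(z02, g, 1), 11.606, tolerance = 0.01)
  expect_equal(zener_decay_constant(z02, g, 5), 1.332, tolerance = 0.01)
  z005 <- zener_from_speeds(4, 3, g, tau = 0.05)
  expect_equal(zener_decay_constant(z005, g, 1), 45.11, tolerance = 0.01)
  expect_equal(zener_decay_constant(z005, g, 8), 0.820, tolerance = 0.01)
  expect_equal(zener_decay_constant(z005, g, 10), 0.588, tolerance = 0.01)
})

test_that("essential spectrum and tau_eq are the same min/max pair", {
  g <- validation_tube()
  z2 <- zener_from_speeds(4, 3, g, tau = 2)
  expect_equal(zener_essential_spectrum(z2), 11.11, tolerance = 1e-3)
  expect_equal(zener_tau_eq(z2), zener_essential_spectrum(z2))
  z005 <- zener_from_speeds(4, 3, g, tau = 0.05)
  expect_equal(zener_essential_spectrum(z005), 0.278, tolerance = 1e-3)
  # E1 = 2 E0: both branch arguments coincide
  zb <- zener_material(E0 = 1e6, E1 = 2e6, tau = 0.5)
  expect_equal(zener_tau_eq(zb), 3 * 0.5)
  # both branches bound tau_eq from below by 3 tau, continuously at E1 = 2E0
  za <- zener_material(E0 = 3e6, E1 = 1e6, tau = 0.5)   # E1 < 2 E0
  expect_equal(zener_tau_eq(za), 2 * 0.5 * 4e6 / 1e6)
  expect_gt(zener_tau_eq(za), 3 * 0.5)
  zc <- zener_material(E0 = 0.5e6, E1 = 3e6, tau = 0.5) # E1 >= 2 E0
  expect_equal(zener_tau_eq(zc), 0.5 * 3.5e6 / 0.5e6)
  expect_gte(zener_tau_eq(zc), 3 * 0.5)
})

test_that("decay constants approach the essential spectrum monotonically", {
  g <- validation_tube()
  z2 <- zener_from_speeds(4, 3, g, tau = 2)   # E1 < 2 E0
  taus <- sapply(1:40, function(n) zener_decay_constant(z2, g, n))
  expect_true(all(diff(taus) < 0))
  expect_true(all(taus > zener_essential_spectrum(z2)))
  expect_equal(taus[40], zener_essential_spectrum(z2), tolerance = 0.01)
})

test_that("Zener with E0 = 0 reproduces the Maxwell spectrum", {
  g <- validation_tube()
  m <- maxwell_from_speed(5, g, tau = 0.2)
  z0 <- zener_material(0, m$E1, 0.2)
  for (n in 1:5) {
    r <- zener_mode_roots(z0, g, n)
    r <- sort(Re(r[abs(Im(r)) < 1e-9]))
    spn <- maxwell_spectrum(m, g, n)$modes
    mu <- c(Re(spn$rate1[n]), Re(spn$rate2[n]))
    if (spn$regime[n] == "overdamped") {
      expect_equal(r[r > 1e-9], sort(-mu), tolerance = 1e-9)
    }
  }
})

test_that("validity condition reports tau^2 c^2 against the 1 m^2 threshold", {
  g <- validation_tube()
  v <- validity_condition(zener_from_speeds(4, 3, g, tau = 2), g)
  expect_equal(v$value_m2, 100)
  expect_true(v$valid)
  v2 <- validity_condition(zener_from_speeds(4, 3, g, tau = 0.2), g)
  expect_equal(v2$value_m2, 1)
  expect_true(v2$valid)  # threshold is inclusive
  v3 <- validity_condition(zener_from_speeds(4, 3, g, tau = 0.05), g)
  expect_equal(v3$value_m2, 0.0625)
  expect_false(v3$valid)
})

test_that("attenuation and required length are exact inverses", {
  expect_equal(attenuation(1.7, 13.8, 0)$a, 0)
  set.seed(7)
  for (i in 1:50) {
    tau_eq <- runif(1, 0.1, 20)
    cs <- runif(1, 1, 30)
    a <- runif(1, 1e-4, 0.99)
    L <- required_length(tau_eq, cs, a)
    expect_equal(attenuation(tau_eq, cs, L)$a, a, tolerance = 1e-12)
  }
  # monotone in L, saturating at 1
  a_of_L <- sapply(c(1, 2, 5, 50, 5000), function(L)
    attenuation(2, 10, L)$a)
  expect_true(all(diff(a_of_L) > 0))
  expect_equal(a_of_L[5], 1, tolerance = 1e-9)
  expect_error(required_length(1, 1, 1.2), "strictly")
})

test_that("PDMS card predicts about 4 % attenuation in the first meter", {
  z <- pdms_card()
  cs <- wave_speeds(z, carotid_tube())$c
  a <- attenuation(zener_tau_eq(z), cs, 1)$a
  expect_equal(a, 0.04, tolerance = 0.005 / 0.04)
  expect_equal(required_length(zener_tau_eq(z), cs, 0.04), 0.96,
               tolerance = 0.02)
})
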