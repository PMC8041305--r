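# Unit bridge, pair potential, association machinery and state functions.

test_that("number density bridges mg/mL and nm^-3 and round-trips exactly", {
  expect_identical(number_density(0, 14300), 0)
  expect_equal(number_density(90, 14300), 3.790159e-3, tolerance = 1e-6)
  g <- c(0.5, 12, 90, 125, 230)
  rho <- number_density(g, 14300)
  expect_equal(mass_concentration(rho, 14300), g, tolerance = 1e-12)
  expect_error(number_density(-1, 14300), "non-negative")
})

test_that("packing fraction and PY contact value take their known values", {
  expect_identical(packing_fraction(0, 3.43), 0)
  eta90 <- packing_fraction(number_density(90, 14300), 3.43)
  expect_equal(eta90, 0.080083, tolerance = 1e-4)
  eta125 <- packing_fraction(number_density(125, 14300), 3.43)
  expect_equal(eta125, eta90 * 125 / 90, tolerance = 1e-12)  # linear in gamma
  expect_equal(eta125, 0.11123, tolerance = 1e-4)
  expect_error(packing_fraction(0.8, 3.43), "close packing")

  expect_identical(ghs_contact(0), 1)
  expect_equal(ghs_contact(eta90), 1.2290, tolerance = 1e-4)
  expect_true(ghs_contact(0.2) > ghs_contact(0.1) &&
                ghs_contact(0.1) > ghs_contact(0.05))
  expect_error(ghs_contact(1.0), "\\[0, 1\\)")
  expect_error(ghs_contact(-0.1), "\\[0, 1\\)")
})

test_that("configurational pair energy implements core, well and single-bond rule", {
  m <- table2_model()
  eps <- 2000
  up <- matrix(c(1, 0, 0), 1)      # site pointing at the partner
  um <- matrix(c(-1, 0, 0), 1)     # site pointing away
  # hard overlap
  expect_identical(pair_config_energy(0.9 * m$sigma, up, um, m, eps), Inf)
  # far apart: no site can reach
  expect_identical(pair_config_energy(2 * m$sigma, up, um, m, eps), 0)
  # head-on alignment at r = sigma + omega/2: site gap = omega/2 <= omega
  expect_identical(pair_config_energy(m$sigma + m$omega / 2, up, um, m, eps),
                   -eps)
  # two sites of molecule 1 in range of the single site of molecule 2:
  # at most one bond forms
  th <- 0.06
  o1 <- rbind(c(1, 0, 0), c(cos(th), sin(th), 0))
  expect_identical(pair_config_energy(m$sigma + m$omega / 2, o1, um,
                                      protein_model(3.43, 0.18, 2, 14300),
                                      eps),
                   -eps)
})

test_that("closed-form Mayer average matches the Monte-Carlo orientation oracle", {
  m <- table2_model()
  eps <- 2000; temp <- 300
  r <- m$sigma + m$omega / 2
  mc <- mc_mayer(r, temp, eps, m, n = 1e6, seed = 42)
  expect_lt(abs(mayer_angular_average(r, temp, eps, m) - mc$mean), 3 * mc$se)
})

test_that("Mayer average obeys its limits and monotonicities", {
  m <- table2_model()
  r <- seq(m$sigma, m$sigma + m$omega, length.out = 7)
  expect_identical(mayer_angular_average(r, 300, 0, m), rep(0, 7))
  expect_identical(mayer_angular_average(m$sigma + m$omega + 0.01, 300, 2000, m), 0)
  expect_error(mayer_angular_average(0.99 * m$sigma, 300, 2000, m), ">= sigma")
  f <- mayer_angular_average(r[2], 300, 2000, m)
  expect_gt(mayer_angular_average(r[2], 300, 2500, m), f)  # deeper well
  expect_lt(mayer_angular_average(r[2], 350, 2000, m), f)  # hotter
  expect_true(all(mayer_angular_average(r, 300, 2000, m) >= 0))
})

test_that("association strength equals the quadrature of the Mayer average", {
  m <- table2_model()
  expect_identical(association_strength(300, 0.1, m, 0), 0)
  d <- association_strength(300, 0.08, m, 2000)
  expect_equal(d, quad_delta(300, 0.08, m, 2000), tolerance = 1e-8)
  # factorisation: density enters only through the contact value
  r21 <- association_strength(300, 0.2, m, 2000) /
    association_strength(300, 0.1, m, 2000)
  expect_equal(r21, ghs_contact(0.2) / ghs_contact(0.1), tolerance = 1e-12)
  expect_gt(association_strength(300, 0.08, m, 2500), d)
})

test_that("monomer fraction solves the mass-action law in closed form", {
  expect_identical(monomer_fraction(0.01, 0, 10), 1)
  # M rho Delta = 1 gives the golden-ratio root
  expect_equal(monomer_fraction(1, 0.1, 10), (sqrt(5) - 1) / 2,
               tolerance = 1e-14)
  # against bisection of the defining equation
  for (cfg in list(c(3.79e-3, 0.5), c(0.01, 2.8), c(0.02, 40))) {
    expect_equal(monomer_fraction(cfg[1], cfg[2], 10),
                 bisect_X(cfg[1], cfg[2], 10), tolerance = 1e-12)
  }
  # X -> 0 monotonically as bonding diverges
  xs <- monomer_fraction(1, c(1, 10, 100, 1e4), 10)
  expect_true(all(diff(xs) < 0) && xs[4] < 1e-2)
})

test_that("free energy parts behave at the association-free and dilute limits", {
  m <- table2_model()
  rho <- number_density(90, 14300)
  fe0 <- free_energy(rho, 280, m, 0)
  expect_identical(fe0$beta_a_assoc, 0)
  expect_identical(fe0$monomer_fraction, 1)
  expect_equal(fe0$beta_a, fe0$beta_a_ideal + fe0$beta_a_hs)
  fe_dil <- free_energy(1e-10, 280, m, 2250)
  expect_lt(abs(fe_dil$beta_a_hs), 1e-8)
  expect_equal(fe_dil$monomer_fraction, 1, tolerance = 1e-5)
  # association always lowers the free energy, X in (0,1]
  fe <- free_energy(rho, 280, m, 2250)
  expect_lt(fe$beta_a_assoc, 0)
  expect_true(fe$monomer_fraction > 0 && fe$monomer_fraction < 1)
  # association part is exactly the TPT1 expression at the bisected X
  xb <- bisect_X(rho, association_strength(280, fe$eta, m, 2250), 10)
  expect_equal(fe$beta_a_assoc, 10 * (log(xb) - xb / 2 + 0.5),
               tolerance = 1e-12)
})

test_that("pressure and chemical potential match derivatives of the free energy", {
  m <- table2_model()
  # hard-sphere compressibility factor at eta = 0.3 is Carnahan-Starling
  rho03 <- 0.3 / (pi * 3.43^3 / 6)
  expect_equal(osmotic_pressure(rho03, 300, m, 0) / rho03, 3.9738,
               tolerance = 1e-4)
  # ideal-gas limit
  expect_equal(osmotic_pressure(1e-10, 300, m, 0) / 1e-10, 1, tolerance = 1e-8)
  # finite differences at a strongly associating state
  rho <- 0.08 / (pi * 3.43^3 / 6)
  expect_equal(osmotic_pressure(rho, 280, m, 2250),
               fd_pressure(rho, 280, m, 2250), tolerance = 1e-7)
  expect_equal(chemical_potential(rho, 280, m, 2250),
               fd_mu(rho, 280, m, 2250), tolerance = 1e-7)
  # Gibbs-Duhem holds identically
  fe <- free_energy(rho, 280, m, 2250)
  expect_lt(abs(fe$beta_mu - fe$beta_a - fe$beta_pressure / rho), 1e-10)
})

test_that("second virial coefficient has the hard-sphere limit and virial identity", {
  m <- table2_model()
  b0 <- second_virial(298, m, 0)
  expect_equal(b0$B2_nm3, 2 * pi * 3.43^3 / 3, tolerance = 1e-14)
  expect_equal(b0$B2_nm3, 84.5164, tolerance = 1e-6)
  expect_equal(b0$B22_mol_mL_g2, 2.48897e-4, tolerance = 1e-5)
  # monotone decreasing in eps; restored as T -> infinity
  b <- vapply(c(0, 1000, 2000, 2500),
              function(e) second_virial(298, m, e)$B2_nm3, numeric(1))
  expect_true(all(diff(b) < 0))
  expect_equal(second_virial(1e9, m, 2000)$B2_nm3, b0$B2_nm3, tolerance = 1e-5)
  # low-density pressure expansion reproduces B2 (Richardson in rho)
  ee <- function(r) (osmotic_pressure(r, 298, m, 2000) / r - 1) / r
  r1 <- 1e-6; r2 <- 1e-7
  b2_est <- ee(r2) - r2 * (ee(r1) - ee(r2)) / (r1 - r2)
  expect_equal(b2_est, second_virial(298, m, 2000)$B2_nm3, tolerance = 1e-3)
})

test_that("salt law eps(I) is the square-root form with eps(0) = eps0", {
  b <- buffer_interaction("phosphate", eps0 = 2250, salt_coeff = 500)
  expect_identical(epsilon_at_ionic_strength(b, 0), 2250)
  expect_equal(epsilon_at_ionic_strength(b, 0.1), 2250 + 500 * sqrt(0.1),
               tolerance = 1e-12)
  expect_equal(epsilon_at_ionic_strength(b, 0.1), 2408.11, tolerance = 1e-5)
  ii <- seq(0.05, 0.5, by = 0.05)
  expect_true(all(diff(epsilon_at_ionic_strength(b, ii)) > 0))
  expect_error(epsilon_at_ionic_strength(b, -0.1), "non-negative")
})

test_that("model and buffer constructors validate their invariants", {
  expect_error(protein_model(-1, 0.18, 10, 14300), "sigma")
  expect_error(protein_model(3.43, 4, 10, 14300), "omega")
  expect_error(protein_model(3.43, 0.18, 2.5, 14300), "integer")
  m <- table2_model()
  expect_identical(m$site_distance, m$sigma / 2)
  expect_error(buffer_interaction("x", -5, 100), "positive")
  expect_error(buffer_interaction("x", 2000, NaN), "finite")
})
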