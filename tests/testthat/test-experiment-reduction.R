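# Measurement reduction: Stokes-Einstein, kD, Debye/B22, viscometry and
# Jones-Dole fits.

test_that("Stokes-Einstein converts both ways and scales correctly", {
  D <- stokes_einstein(298.15, 0.8900, radius_nm = 1.9)
  expect_equal(D, 1.2914e-10, tolerance = 1e-4)
  rh <- stokes_einstein(298.15, 0.8900, diffusion_m2_s = D)
  expect_equal(rh, 1.9, tolerance = 1e-12)
  expect_equal(stokes_einstein(298.15, 2 * 0.8900, radius_nm = 1.9), D / 2,
               tolerance = 1e-12)
  expect_error(stokes_einstein(298.15, 0.89), "exactly one")
  expect_error(stokes_einstein(-1, 0.89, radius_nm = 1), "positive")
})

test_that("kD fit recovers positive and negative generating slopes exactly", {
  for (kd in c(11.0, -7.1)) {
    s <- gen_dls_series(1.2e-10, kd, noise_sd = 0, seed = 1)
    fit <- fit_interaction_diffusion(s)
    expect_equal(fit$kD_mL_g, kd, tolerance = 1e-9)
    expect_equal(fit$D0_m2_s, 1.2e-10, tolerance = 1e-12)
  }
  # fit window subsets the series
  s <- gen_dls_series(1.2e-10, 11, gammas = seq(4, 70, length.out = 8),
                      noise_sd = 0, seed = 1)
  fitw <- fit_interaction_diffusion(s, window = c(4, 40))
  expect_lt(fitw$n, 8)
  expect_equal(fitw$kD_mL_g, 11, tolerance = 1e-9)
  expect_error(fit_interaction_diffusion(
    dls_series(c(5, 10), c(1e-10, 1.1e-10)), window = c(50, 60)), ">= 2")
})

test_that("SLS reduction is an intensity-invariant toluene normalisation", {
  cfg <- sls_config()
  concs <- seq(0.002, 0.01, length.out = 5)
  # sample counting like toluene means R_sam = R_tol
  s_eq <- sls_series(concs, mcr_cps = rep(3e5, 5), laser_intensity = 10,
                     toluene_count_rate = 3e5, config = cfg)
  red <- reduce_sls(s_eq)
  K <- 4 * pi^2 * 1.332^2 * 0.185^2 / (6.02214076e23 * (632.8e-7)^4)
  expect_equal(red$kc_over_r, K * concs / 14.0e-6, tolerance = 1e-12)
  # joint rescaling of all count rates with the laser cancels
  s1 <- gen_sls_series(14300, 5.9e-4, concs = concs, seed = 2)
  s2 <- s1; s2$points$mcr_cps <- 7 * s2$points$mcr_cps
  s2$toluene_count_rate <- 7 * s2$toluene_count_rate
  expect_equal(reduce_sls(s1)$kc_over_r, reduce_sls(s2)$kc_over_r,
               tolerance = 1e-12)
  # pre-reduced series pass through
  pre <- sls_series(concs, kc_over_r = red$kc_over_r)
  expect_identical(reduce_sls(pre)$kc_over_r, red$kc_over_r)
  expect_error(sls_series(concs, mcr_cps = rep(1, 5)), "toluene")
})

test_that("Debye fit recovers Mw and B22 of either sign exactly", {
  for (b22 in c(5.9e-4, -1.2e-4)) {
    s <- gen_sls_series(14300, b22, noise_frac = 0, seed = 1)
    fit <- debye_fit(reduce_sls(s))
    expect_equal(fit$Mw_g_mol, 14300, tolerance = 1e-8)
    expect_equal(fit$B22_mol_mL_g2, b22, tolerance = 1e-8)
    expect_true(fit$Mw_defined)
  }
  # non-positive intercept: Mw flagged undefined, slope still reported
  pts <- data.frame(conc_g_ml = c(0.002, 0.006, 0.01),
                    kc_over_r = -2e-5 + 2 * 3e-4 * c(0.002, 0.006, 0.01))
  expect_warning(fit <- debye_fit(pts), "non-positive")
  expect_false(fit$Mw_defined)
  expect_true(is.na(fit$Mw_g_mol))
  expect_equal(fit$B22_mol_mL_g2, 3e-4, tolerance = 1e-9)
})

test_that("flow-time reduction reproduces the reference and is linear in t", {
  ref <- list(flow_s = 100, density_g_cm3 = 0.9970, eta_mPas = 0.8900)
  s <- viscosity_series(c(0.0, 0.05), flow_s = c(100, 200),
                        density_g_cm3 = c(0.9970, 0.9970), reference = ref)
  red <- viscosity_from_flow(s)
  expect_equal(red$eta_mPas[1], 0.8900, tolerance = 1e-12)
  expect_equal(red$eta_rel[1], 1, tolerance = 1e-12)
  expect_equal(red$eta_rel[2], 2, tolerance = 1e-12)  # doubled flow time
  expect_error(viscosity_series(0.05, flow_s = 120, density_g_cm3 = 1,
                                reference = list(flow_s = 0,
                                                 density_g_cm3 = 1,
                                                 eta_mPas = 0.89)),
               "positive")
})

test_that("Jones-Dole fit recovers A and B, optionally with A pinned", {
  concs <- seq(0.02, 0.1, by = 0.02)
  er <- 1 + 0.01 * sqrt(concs) + 0.50 * concs
  fit <- jones_dole_fit(concs, er)
  expect_equal(fit$A, 0.01, tolerance = 1e-9)
  expect_equal(fit$B_L_mol, 0.50, tolerance = 1e-9)
  fitp <- jones_dole_fit(concs, er, fix_A = 0.01)
  expect_true(fitp$A_fixed)
  expect_equal(fitp$B_L_mol, 0.50, tolerance = 1e-9)
  expect_error(jones_dole_fit(rep(0.05, 3), c(1, 1, 1)), "distinct")
})

test_that("reduction fits are unbiased under their stated noise models", {
  nrep <- 300
  kd_hat <- vapply(seq_len(nrep), function(s) {
    fit_interaction_diffusion(gen_dls_series(1.2e-10, 11.0, noise_sd = 1.2e-12,
                                             seed = s))$kD_mL_g
  }, numeric(1))
  expect_lt(abs(mean(kd_hat) - 11.0), 2 * stats::sd(kd_hat) / sqrt(nrep))
  expect_lt(abs(mean(kd_hat) - 11.0), 0.1)
  b_hat <- vapply(seq_len(nrep), function(s) {
    v <- gen_viscosity_series(0.01, 0.50, noise_sd = 0.001, seed = s)
    jones_dole_fit(v$points$conc_M, v$points$eta_rel)$B_L_mol
  }, numeric(1))
  expect_lt(abs(mean(b_hat) - 0.50), 2 * stats::sd(b_hat) / sqrt(nrep))
  # Table-scale SEs: spread of B across replicates in the +/-0.02-0.15 range
  expect_gt(stats::sd(b_hat), 0.005)
  expect_lt(stats::sd(b_hat), 0.2)
})
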