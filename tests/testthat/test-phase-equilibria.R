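# Spinodal, critical point, binodal and cloud-point solvers.

m <- table2_model()

test_that("spinodal exists only below the critical point and has zero slope", {
  crit <- critical_point(m, 2250)
  expect_null(spinodal_densities(crit$temperature * 1.5, m, 2250))
  sp <- spinodal_densities(0.95 * crit$temperature, m, 2250)
  expect_lt(sp[1], sp[2])
  # defining property: numerically differentiated pressure is flat there
  h <- 1e-7
  for (r0 in sp) {
    slope <- (osmotic_pressure(r0 + h, 0.95 * crit$temperature, m, 2250) -
                osmotic_pressure(r0 - h, 0.95 * crit$temperature, m, 2250)) / (2 * h)
    expect_lt(abs(slope), 1e-9)
  }
})

test_that("critical point solves both derivative conditions and scales with eps", {
  crit <- critical_point(m, 2250)
  expect_lt(abs(crit$residuals[1]), 1e-9)
  expect_lt(abs(crit$residuals[2]), 1e-6)
  # deeper well -> higher critical temperature
  crit_lo <- critical_point(m, 1940)
  expect_gt(crit$temperature, crit_lo$temperature)
  # temperature enters only through beta*eps: T_c/eps is invariant
  expect_equal(crit$temperature / 2250, crit_lo$temperature / 1940,
               tolerance = 1e-8)
  # simple critical point: third density derivative does not vanish
  h <- crit$rho * 1e-3
  d3 <- (osmotic_pressure(crit$rho + 2 * h, crit$temperature, m, 2250) -
           2 * osmotic_pressure(crit$rho + h, crit$temperature, m, 2250) +
           2 * osmotic_pressure(crit$rho - h, crit$temperature, m, 2250) -
           osmotic_pressure(crit$rho - 2 * h, crit$temperature, m, 2250)) /
    (2 * h^3)
  expect_gt(abs(d3) * crit$rho^3, 1e-6)
})

test_that("coexistence points satisfy equal pressure and chemical potential", {
  crit <- critical_point(m, 2250)
  for (frac in c(0.999, 0.9, 0.8)) {
    cp <- coexistence_at_temperature(frac * crit$temperature, m, 2250,
                                     crit = crit)
    expect_lt(cp$rho_dilute, cp$rho_dense)
    expect_lt(abs(cp$residuals[1]), 1e-8)
    expect_lt(abs(cp$residuals[2]), 1e-8)
    if (frac == 0.999) {  # branches close on the critical density
      expect_equal(cp$rho_dilute, crit$rho, tolerance = 0.1)
      expect_equal(cp$rho_dense, crit$rho, tolerance = 0.1)
    }
    # binodal straddles the spinodal at the same temperature
    sp <- spinodal_densities(frac * crit$temperature, m, 2250)
    expect_lt(cp$rho_dilute, sp[1])
    expect_gt(cp$rho_dense, sp[2])
  }
  expect_error(coexistence_at_temperature(crit$temperature + 1, m, 2250,
                                          crit = crit), "critical")
})

test_that("solver densities agree with the common-tangent grid oracle", {
  crit <- critical_point(m, 2250)
  for (frac in c(0.97, 0.9, 0.8)) {
    tt <- frac * crit$temperature
    cp <- coexistence_at_temperature(tt, m, 2250, crit = crit)
    ct <- ct_oracle(tt, m, 2250)
    expect_false(is.null(ct))
    expect_equal(cp$rho_dilute, ct[1], tolerance = 1e-3)
    expect_equal(cp$rho_dense, ct[2], tolerance = 1e-3)
  }
})

test_that("binodal curve is a deterministic dome with monotone branches", {
  bc <- binodal_curve(m, 2250, n_temperatures = 25)
  pts <- bc$points
  expect_equal(nrow(pts), 25)
  # dome: every temperature below T_c, approaching it at the top
  expect_true(all(pts$T_K < bc$critical_temperature))
  expect_equal(max(pts$T_K), bc$critical_temperature, tolerance = 2e-3)
  # dilute branch decreases and dense branch increases on cooling
  o <- order(pts$T_K, decreasing = TRUE)
  expect_true(all(diff(pts$rho_dilute_nm3[o]) < 0))
  expect_true(all(diff(pts$rho_dense_nm3[o]) > 0))
  # dilute branch empties out far below T_c
  expect_lt(min(pts$rho_dilute_nm3) / bc$critical_density, 1e-4)
  expect_true(all(abs(pts$res_beta_pi) < 1e-8))
  expect_true(all(abs(pts$res_beta_mu) < 1e-8))
  # byte-identical rerun
  bc2 <- binodal_curve(m, 2250, n_temperatures = 25)
  expect_identical(bc$points, bc2$points)
})

test_that("reduced dome width at corresponding state grows as sites are removed", {
  m6 <- protein_model(3.43, 0.18, 6, 14300)
  w <- function(mod) {
    cr <- critical_point(mod, 2250)
    cp <- coexistence_at_temperature(0.9 * cr$temperature, mod, 2250, crit = cr)
    (cp$rho_dense - cp$rho_dilute) / cr$rho
  }
  expect_gt(w(m6), w(m))
})

test_that("cloud point inverts the binodal and moves the right way", {
  bc <- binodal_curve(m, 2250, n_temperatures = 20, t_min = 200)
  # round trip through the dilute branch
  for (i in c(3, 10, 16)) {
    tcl <- cloud_point_temperature(bc$points$gamma_dilute_mg_ml[i], m, 2250)
    expect_lt(abs(as.numeric(tcl) - bc$points$T_K[i]), 2e-3)
    expect_identical(attr(tcl, "branch"), "dilute")
  }
  # and the dense branch
  tcd <- cloud_point_temperature(bc$points$gamma_dense_mg_ml[10], m, 2250)
  expect_lt(abs(as.numeric(tcd) - bc$points$T_K[10]), 2e-3)
  expect_identical(attr(tcd, "branch"), "dense")
  # more protein (left of the apex) clouds at higher temperature
  expect_gt(cloud_point_temperature(125, m, 2250),
            cloud_point_temperature(90, m, 2250))
  # added salt deepens the well and raises the cloud point
  b <- buffer_interaction("phosphate", 2250, 500)
  t_salt <- vapply(c(0, 0.2, 0.5), function(I)
    as.numeric(cloud_point_temperature(90, m, b, ionic_strength = I)),
    numeric(1))
  expect_true(all(diff(t_salt) > 0))
  # critical concentration returns T_c itself
  crit <- critical_point(m, 2250)
  tc_gamma <- cloud_point_temperature(crit$gamma_mg_ml, m, 2250)
  expect_equal(as.numeric(tc_gamma), crit$temperature, tolerance = 1e-6)
  # unreachable concentration errors out
  expect_error(cloud_point_temperature(90, m, 2250, t_min = 258),
               "outside the coexistence dome")
})
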