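test_that("effective viscosity has the Newtonian and high-shear limits", {
  newt <- hb_params(0, 2, 1)
  expect_equal(effective_viscosity(c(0, 1e-3, 1, 1e3), newt), rep(2, 4))

  hb <- hb_params(10, 1, 1, m_reg = 1000)
  g <- 1e6
  expect_equal(effective_viscosity(g, hb), 1 + 10 / g, tolerance = 1e-9)

  # regularized stress approaches the ideal law once m_reg*gdot is large
  g <- 10^seq(log10(31 / hb$m_reg), 3, length.out = 50)
  expect_lt(max(abs(shear_stress(g, hb) / hb_ideal_stress(g, 10, 1, 1) - 1)), 1e-6)
})

test_that("stress is zero at rest, continuous and monotone in shear rate", {
  expect_identical(shear_stress(0, hb_params(50, 20, 0.4)), 0)
  for (p in list(c(0, 2, 1), c(50, 20, 0.4), c(200, 5, 0.8), c(5, 1, 1.2))) {
    hb <- hb_params(p[1], p[2], p[3])
    g <- 10^seq(-3, 3, length.out = 400)
    tau <- shear_stress(g, hb)
    expect_true(all(diff(tau) > 0), info = paste(p, collapse = "/"))
    # shear thinning: viscosity non-increasing for n <= 1
    if (p[3] <= 1) expect_true(all(diff(effective_viscosity(g, hb)) <= 1e-12))
  }
})

test_that("regularized stress converges to ideal HB as m_reg grows", {
  g <- 10^seq(-2, 2, length.out = 100)
  errs <- vapply(c(1e2, 1e3, 1e4), function(m) {
    hb <- hb_params(30, 8, 0.5, m_reg = m)
    max(abs(shear_stress(g, hb) / hb_ideal_stress(g, 30, 8, 0.5) - 1))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("parameter validation rejects unphysical values", {
  expect_error(hb_params(-1, 1, 1), "tau_y")
  expect_error(hb_params(0, 0, 1), "K")
  expect_error(hb_params(0, 1, -2), "n")
  expect_error(effective_viscosity(c(1, NA), hb_params(0, 1, 1)), "finite")
  expect_error(effective_viscosity(-1, hb_params(0, 1, 1)), "finite")
})

test_that("flow-curve fit round-trips noise-free parameters within 1%", {
  fit <- fit_flow_curve(synth_flow_curve(50, 20, 0.4))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["tau_y"]), 50, tolerance = 0.01)
  expect_equal(unname(coef(fit)["K"]), 20, tolerance = 0.01)
  expect_equal(unname(coef(fit)["n"]), 0.4, tolerance = 0.01)
  expect_lt(fit$residual_rms_log, 1e-6)
})

test_that("flow-curve fit degenerates cleanly and tolerates noise", {
  # Newtonian data: fitted yield stress below 1% of the maximum stress
  cv <- synth_flow_curve(0, 5, 1)
  fit <- fit_flow_curve(cv)
  expect_lt(coef(fit)["tau_y"], 0.01 * max(cv$stresses))

  # 5% multiplicative log-normal noise: parameters within 15%
  fit <- fit_flow_curve(synth_flow_curve(50, 20, 0.4, noise_sd = 0.05, seed = 42))
  expect_equal(unname(coef(fit)["tau_y"]), 50, tolerance = 0.15)
  expect_equal(unname(coef(fit)["K"]), 20, tolerance = 0.15)
  expect_equal(unname(coef(fit)["n"]), 0.4, tolerance = 0.15)
})

test_that("flow curves round-trip through CSV", {
  cv <- synth_flow_curve(30, 10, 0.5, n_pts = 12)
  path <- tempfile(fileext = ".csv")
  write_flow_curve_csv(cv, path)
  cv2 <- read_flow_curve_csv(path)
  expect_equal(cv2$shear_rates, cv$shear_rates)
  expect_equal(cv2$stresses, cv$stresses)
})

test_that("recovery percentage is the plateau ratio of the two passes", {
  tr <- synth_tearing_trace(1)
  expect_equal(recovery_percent(tr), 100)
  expect_equal(recovery_percent(synth_tearing_trace(0.5)), 50)
  # exponential recovery to 0.95 with 2% noise: 95 +- 1
  expect_equal(recovery_percent(synth_tearing_trace(0.95, noise_sd = 0.02,
                                                    seed = 7)), 95,
               tolerance = 1 / 95)
  dead <- tearing_trace(1:10, rep(0, 10), rep(0, 10))
  expect_error(recovery_percent(dead), "plateau")
})

test_that("tearing traces round-trip through CSV", {
  tr <- synth_tearing_trace(0.8, n = 50, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_tearing_trace_csv(tr, path)
  tr2 <- read_tearing_trace_csv(path)
  expect_equal(tr2$torque_first, tr$torque_first)
  expect_equal(tr2$torque_second, tr$torque_second)
})

test_that("yield-capillary number is linear and correctly scaled", {
  expect_equal(yield_capillary_number(100, 0.025, 250e-6), 1)
  expect_equal(yield_capillary_number(100, 0.025, 500e-6),
               2 * yield_capillary_number(100, 0.025, 250e-6))
  expect_error(yield_capillary_number(0, 0.025, 1e-4), "positive")
  # strictly increasing in tau_y across the catalog at fixed sigma, R
  cat <- materials_catalog()
  Y <- vapply(cat[c("M1", "M1A", "M1B", "M1C", "M1D", "M2")], function(m)
    yield_capillary_number(m$hb$tau_y, 0.025, 250e-6), 0)
  expect_true(all(diff(Y) > 0))
})

test_that("regime classification follows recovery then plastocapillarity", {
  cat <- materials_catalog()
  R <- 250e-6
  expect_identical(classify_regime(cat$M3, R, recovery = 50), "M3")
  expect_identical(classify_regime(cat$M2, R, recovery = 96), "M2")
  low <- ap_material("weak", hb_params(0.5, 5, 0.6))
  expect_identical(classify_regime(low, R, recovery = 96), "M1")
  # monotone: raising tau_y at fixed sigma, R, recovery never demotes M2 to M1
  taus <- 10^seq(-1, 3, length.out = 30)
  reg <- vapply(taus, function(ty)
    classify_regime(ap_material("x", hb_params(ty, 5, 0.6)), R, 96), "")
  expect_true(all(diff(reg == "M2") >= 0))
})

test_that("materials catalog round-trips through YAML config", {
  cat <- materials_catalog()
  expect_true(all(c("M1", "M1A", "M1B", "M1C", "M1D", "M2", "M3") %in% names(cat)))
  path <- tempfile(fileext = ".yaml")
  write_materials_catalog(cat, path)
  cat2 <- read_materials_catalog(path)
  expect_equal(cat2$M2$hb$tau_y, cat$M2$hb$tau_y)
  expect_equal(cat2$M3$storage_modulus, cat$M3$storage_modulus)
})
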