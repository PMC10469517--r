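# Evaporative-flux physics: Buck VPD, flux conversions, temperature
# corrections. Published reference values were verified against the source
# before freezing.

test_that("Buck VPD reproduces the stated conditions and limits", {
  expect_equal(vapor_pressure_deficit(heat_air()), 6.5, tolerance = 0.05 / 6.5)
  expect_equal(vapor_pressure_deficit(growth_air()), 1.4, tolerance = 0.05 / 1.4)
  # saturated air: zero deficit at any temperature
  for (t in c(0, 20, 40)) {
    expect_equal(vapor_pressure_deficit(air_state(t, 100)), 0)
  }
})

test_that("VPD is monotone: increasing in T, decreasing in RH", {
  temps <- seq(0, 50, by = 5)
  v_t <- vapor_pressure_deficit(air_state(temps, rep(60, length(temps))))
  expect_true(all(diff(v_t) > 0))
  rhs <- seq(0, 100, by = 10)
  v_rh <- vapor_pressure_deficit(air_state(rep(25, length(rhs)), rhs))
  expect_true(all(diff(v_rh) < 0))
})

test_that("air_state validates its domain", {
  expect_error(air_state(25, 120), "relative_humidity")
  expect_error(air_state(80, 50), "temperature")
  expect_error(air_state(25, 50, pressure = -1), "pressure")
})

test_that("flux conversion matches the measured-parameter table", {
  # flower and leaf residual transpiration from residual conductance
  expect_lt(abs(convert_flux(13.98, heat_air(), "g2E") - 0.90), 0.01)
  expect_lt(abs(convert_flux(12.15, growth_air(), "g2E") - 0.17), 0.01)
  expect_lt(abs(convert_flux(5.01, heat_air(), "g2E") - 0.32), 0.01)
  # the leaf 20 degC cell prints 0.06 for a computed 0.065
  expect_lt(abs(convert_flux(4.68, growth_air(), "g2E") - 0.065), 0.01)
})

test_that("flux conversion round-trips and guards the VPD singularity", {
  cases <- expand.grid(g = c(0.5, 4.68, 13.98), t = c(15, 25, 40),
                       rh = c(10, 55, 95))
  for (i in seq_len(nrow(cases))) {
    air <- air_state(cases$t[i], cases$rh[i])
    e <- convert_flux(cases$g[i], air, "g2E")
    expect_equal(convert_flux(e, air, "E2g"), cases$g[i],
                 tolerance = 1e-12)
  }
  expect_error(convert_flux(1, air_state(25, 100), "E2g"), "singular")
})

test_that("viscosity ratio matches the empirical fit and its symmetries", {
  expect_equal(water_viscosity_ratio(20, 40), 1.534, tolerance = 1e-3)
  expect_identical(water_viscosity_ratio(20, 20), 1)
  expect_equal(water_viscosity_ratio(40, 20) * water_viscosity_ratio(20, 40),
               1, tolerance = 1e-12)
  expect_error(water_viscosity_ratio(20, 75), "0, 60")
})

test_that("conductance correction reproduces the 40 degC K_max cells", {
  expect_equal(correct_conductance(2.60, 20, 40), 3.99, tolerance = 0.01)
  expect_equal(correct_conductance(8.57, 20, 40), 13.14, tolerance = 0.02)
  expect_identical(correct_conductance(5, 20, 20), 5)
  expect_error(correct_conductance(-1, 20, 40), "non-negative")
})

test_that("conductance correction is multiplicative across temperatures", {
  k <- 2.60
  expect_equal(correct_conductance(correct_conductance(k, 20, 30), 30, 40),
               correct_conductance(k, 20, 40), tolerance = 1e-9)
})

test_that("gravimetric conversion follows hand arithmetic and scaling", {
  # 0.9 mg over 10 min and 10 cm2: (0.0009/18.015*1000)/(600*0.001)
  expect_equal(mass_loss_to_flux(0.0009, 600, 0.001),
               (0.0009 / 18.015 * 1000) / (600 * 0.001))
  expect_equal(mass_loss_to_flux(0.0009, 600, 0.001), 0.0833, tolerance = 1e-3)
  expect_identical(mass_loss_to_flux(0, 600, 0.001), 0)
  expect_equal(mass_loss_to_flux(0.001, 600, 0.002),
               mass_loss_to_flux(0.001, 600, 0.001) / 2)
  expect_error(mass_loss_to_flux(0.001, -1, 0.001), "positive")
})

test_that("surface tension ratio is near-unity and decreasing", {
  expect_identical(surface_tension_ratio(20, 20), 1)
  expect_equal(surface_tension_ratio(20, 40), 0.956, tolerance = 0.005)
  sig <- water_surface_tension(seq(0, 60, by = 5))
  expect_true(all(diff(sig) < 0))
})

test_that("batch conversion table appends converted values", {
  df <- data.frame(temp_C = c(40, 20), rh_pct = c(12, 40),
                   value = c(13.98, 0.17), direction = c("g2E", "E2g"))
  out <- convert_flux_table(df)
  expect_equal(out$converted[1], 0.90, tolerance = 0.01)
  expect_equal(out$converted[2], 12.28, tolerance = 0.1)
  expect_error(convert_flux_table(df[1:2]), "columns")
})
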