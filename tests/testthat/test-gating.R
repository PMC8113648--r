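test_that("open-fraction bands reproduce the anchored gating regimes", {
  tab <- gating_table()
  expect_equal(orai_open_fraction(tab, 400), 0.21)  # full ER
  expect_equal(orai_open_fraction(tab, 330), 0.50)  # locally depleted
  expect_equal(orai_open_fraction(tab, 365), 0.21)  # above 360: minimal only
  expect_equal(orai_open_fraction(tab, 100), 1.00)  # deep depletion
  # vectorised, piecewise constant, values come from the table
  cs <- seq(0, 1000, by = 0.5)
  f <- orai_open_fraction(tab, cs)
  expect_true(all(f %in% tab$fractions))
  expect_true(all(diff(f) * diff(cs) <= 0))  # non-increasing in cs
  # the half-open state carries > 2x the full-ER flux
  expect_gt(orai_open_fraction(tab, 330) / orai_open_fraction(tab, 400), 2)
  expect_error(orai_open_fraction(tab, -1),
               class = "socesim_invalid_argument")
})

test_that("gating-table validation rejects malformed tables", {
  expect_error(gating_table(c(360, 250), c(0.2, 0.5)),
               class = "socesim_invalid_argument")
  expect_error(gating_table(c(250, 360, 150), c(0.2, 0.5, 0.8, 1)),
               class = "socesim_invalid_argument")
  expect_error(gating_table(c(360, 250, 150), c(0.2, 0.5, 0.8, 1.2)),
               class = "socesim_invalid_argument")
  expect_error(gating_table(c(360, 250, 150), c(0.5, 0.2, 0.8, 1)),
               class = "socesim_invalid_argument")
})

test_that("ORAI molar rates and ion counts follow f I/(zF)", {
  p <- flux_params()
  expect_identical(orai_molar_rate(0, p), 0)
  expect_equal(orai_molar_rate(0.21, p), 2.2853e-21, tolerance = 1e-4)
  expect_equal(orai_molar_rate(1, p), 1.0882e-20, tolerance = 1e-4)
  expect_equal(ions_entered(5, 0.21, 0.044, p), 302.78, tolerance = 1e-4)
  expect_equal(ions_entered(1, 0.21, 0.044, p), 302.78 / 5, tolerance = 1e-4)
  expect_identical(ions_entered(7, 0, 1, p), 0)
  expect_error(orai_molar_rate(1.2, p), class = "socesim_invalid_argument")
  expect_error(ions_entered(1, 0.21, -1, p),
               class = "socesim_invalid_argument")
})

test_that("IP3R rate is the gradient-scaled unitary rate", {
  p <- flux_params()
  base <- p$I_IP3R / (p$z * p$F)
  expect_equal(ip3r_molar_rate(400, 0.030, p), base, tolerance = 1e-12)
  expect_equal(ip3r_molar_rate(400, 0.030, p), 3.3166e-19, tolerance = 1e-4)
  expect_equal(ip3r_molar_rate(250, 250, p), 0)
  expect_equal(ip3r_molar_rate(330, 16, p), 2.6037e-19, tolerance = 1e-4)
  # linear in the gradient, antisymmetric under swapping the mouths
  for (pair in list(c(350, 10), c(200, 50), c(100, 150))) {
    r1 <- ip3r_molar_rate(pair[1], pair[2], p)
    expect_equal(ip3r_molar_rate(pair[2], pair[1], p), -r1)
    expect_equal(r1 / base,
                 (pair[1] - pair[2]) / (p$C_S0 - p$C_C0 * 1e-3),
                 tolerance = 1e-9)
  }
})

test_that("SERCA pump: rest equilibrium, monotonicity and saturation", {
  p <- flux_params()
  expect_equal(p$serca_KS / p$serca_KC, (p$C_S0 * 1e3) / p$C_C0)
  expect_lt(abs(serca_molar_rate(0.030, 400, p)), 1e-35)  # exact rest balance
  expect_equal(serca_molar_rate(16, 400, p) / p$serca_Vmax, 0.0929,
               tolerance = 1e-2)  # far from saturation at the Fig-9 regime
  cc <- c(0.01, 0.1, 1, 10, 100, 1e4, 1e6)
  r <- serca_molar_rate(cc, 400, p)
  expect_true(all(diff(r) > 0))                   # increasing in cytosolic Ca
  expect_true(all(abs(r) <= p$serca_Vmax))
  expect_gt(serca_molar_rate(1e6, 400, p), 0.999 * p$serca_Vmax)
  cs <- c(100, 200, 400, 800)
  expect_true(all(diff(serca_molar_rate(1, cs, p)) < 0))  # decreasing in ER Ca
  expect_error(serca_molar_rate(-1, 400, p),
               class = "socesim_invalid_argument")
})

test_that("flux parameter validation and rest-equilibrium constraint", {
  expect_error(flux_params(D_S = -10), class = "socesim_invalid_argument")
  p <- flux_params(C_S0 = 500, C_C0 = 50, serca_KC = 40)
  expect_equal(p$serca_KS, 40 * 500e3 / 50)
  expect_lt(abs(serca_molar_rate(0.050, 500, p)), 1e-35)
  expect_identical(p$z, 2)
})
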