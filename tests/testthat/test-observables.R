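test_that("peaks and sensing averages at rest are the resting values", {
  s <- sol_rest()
  expect_equal(as.numeric(peak_at_patch(s, "ORAI", 1)), 0.03,
               tolerance = 1e-9)
  expect_equal(as.numeric(peak_at_patch(s, "SERCA", 3, side = "er")), 400,
               tolerance = 1e-9)
  expect_equal(sensing_average(s, 4), 400, tolerance = 1e-9)
  expect_error(peak_at_patch(s, "ORAI", 1, side = "er"),
               class = "socesim_invalid_argument")
  expect_error(peak_at_patch(s, "IP3R", 99),
               class = "socesim_invalid_argument")
  expect_error(sensing_average(s, 0), class = "socesim_invalid_argument")
})

test_that("ion bookkeeping: counts, sub-unity occupancy, Little's law", {
  s <- sol_orai5()
  bk <- ion_bookkeeping(s)
  expect_equal(bk$ions_entered, 302.78, tolerance = 1e-3)
  expect_lt(bk$free_ions_junction, 1)
  expect_gt(bk$free_ions_junction, 0.01)
  # Little's law identity: residence * influx = steady content
  influx_ions <- sum(s$Q_orai) * socesim_constants$avogadro
  expect_equal(bk$residence_time_s * influx_ions, bk$free_ions_junction,
               tolerance = 1e-12)
  # order of magnitude: the diffusive escape time R^2/(4D) ~ 1e-5 s
  expect_gt(bk$residence_time_s, 3e-6)
  expect_lt(bk$residence_time_s, 1e-4)
  # no influx -> residence time is not available
  expect_true(is.na(ion_bookkeeping(sol_rest())$residence_time_s))
})

test_that("spatial extent is non-increasing in the threshold", {
  s <- sol_orai5()
  thetas <- c(50, 100, 200, 400, 800)
  ext <- vapply(thetas, function(t) spatial_extent(s, t, n = 101), 0)
  expect_true(all(diff(ext) <= 0))
  expect_gt(ext[1], 0)
  expect_equal(spatial_extent(s, 1e9, n = 51), 0)
  expect_error(spatial_extent(s, -5), class = "socesim_invalid_argument")
  expect_error(spatial_extent(s, 100, plane_depth = 1e4),
               class = "socesim_invalid_argument")
})

test_that("SERCA operating points sit far below saturation and order by
           proximity to the open receptors", {
  p <- flux_params()
  # ORAI-only microdomain: pumps barely move
  s <- sol_orai5()
  ops <- lapply(1:10, function(i) serca_operating_point(s, i))
  rates <- vapply(ops, function(o) o$rate, 0)
  expect_true(all(rates < 1e-3 * p$serca_Vmax))
  expect_true(all(vapply(ops, function(o) o$cs_mouth_uM, 0) <= 402))
  # four nearest vs four furthest receptors from the reference pump
  near <- solve_steady(preset_scenario("fig9", variant = "nearest",
                                       mesh = coarse_mesh()))
  far <- solve_steady(preset_scenario("fig9", variant = "furthest",
                                      mesh = coarse_mesh()))
  op_n <- serca_operating_point(near, 1)
  op_f <- serca_operating_point(far, 1)
  expect_gt(op_n$cc_mouth_uM, op_f$cc_mouth_uM)
  expect_lt(max(abs(near$R_serca)), 0.5 * p$serca_Vmax)  # not saturated
  expect_error(serca_operating_point(s, 11),
               class = "socesim_invalid_argument")
})

test_that("cross-sections carry both fields with separate domains", {
  s <- sol_rest()
  cs <- cross_section(s, axis = "y", value = 0, n1 = 41, n2 = 41)
  expect_equal(dim(cs$cc), c(41, 41))
  expect_equal(dim(cs$cs), c(41, 41))
  expect_equal(unique(stats::na.omit(as.numeric(cs$cc))), 0.03,
               tolerance = 1e-9)
  expect_equal(unique(stats::na.omit(as.numeric(cs$cs))), 400,
               tolerance = 1e-9)
  # the two sub-domains tile the plane: each point is in exactly one field
  expect_true(all(xor(is.na(cs$cc), is.na(cs$cs))))
  expect_error(cross_section(s, axis = "y", value = 1e4),
               class = "socesim_invalid_argument")
  # an open-receptor scenario shows a depletion halo in the ER panel
  cs2 <- cross_section(sol_ip3r1(), axis = "y", value = 0, n1 = 81, n2 = 81)
  expect_lt(min(cs2$cs, na.rm = TRUE), 399)
  expect_lte(max(cs2$cs, na.rm = TRUE), 400 * 1.005)
})

test_that("ER field honours its physical bounds in driven scenarios", {
  s <- sol_ip3r1()
  sub <- as.matrix(expand.grid(x = seq(-180, 180, by = 20),
                               y = seq(-180, 180, by = 20),
                               z = seq(20, 490, by = 30)))
  cs <- eval_conc(s, sub, "er")
  cs <- cs[!is.na(cs)]
  expect_true(all(cs >= 0))
  expect_true(all(molm3_to_uM(cs) <= 402))
  cc <- eval_conc(s, sub, "cyto")
  expect_true(all(cc[!is.na(cc)] >= 0))
})

test_that("observable sets collect one tidy row per scenario", {
  obs <- observable_set(sol_orai5(), theta = 100, label = "orai5")
  expect_equal(nrow(obs), 1)
  expect_equal(obs$n_orai_open, 5)
  expect_gt(obs$spatial_extent_um2, 0)
  expect_equal(obs$max_orai_f, 0.21)
  expect_lt(obs$conservation_rel_err, 0.01)
})
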