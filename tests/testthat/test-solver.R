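test_that("no open channels leaves both fields exactly at rest", {
  s <- sol_rest()
  expect_lt(max(abs(s$w$cyto)), 1e-20)
  expect_lt(max(abs(s$w$er)), 1e-20)
  expect_equal(junction_amplitude(s), 0, tolerance = 1e-12)
  pts <- rbind(c(0, 0, 7.5), c(150, 0, 300), c(0, 180, 490))
  cc <- eval_conc(s, pts, "cyto")
  expect_equal(cc[!is.na(cc)], rep(nM_to_molm3(30), sum(!is.na(cc))))
  cs <- eval_conc(s, rbind(c(0, 0, 300)), "er")
  expect_equal(cs, uM_to_molm3(400))
  expect_equal(molm3_to_uM(s$sensed), rep(400, 8), tolerance = 1e-9)
})

test_that("steady-state boundary fluxes balance to under 1%", {
  for (s in list(sol_orai5(), sol_ip3r1())) {
    expect_lt(s$conservation$rel_err, 0.01)
    expect_lt(s$conservation$rel_err_er, 0.01)
  }
})

test_that("with pumps off the solution superposes linearly", {
  g <- geom_default()
  lay <- channel_layout(g, n_serca = 0, n_ip3r = 0)
  mk <- function(open) solve_steady(
    scenario(g, lay, open_orai = open, mesh = coarse_mesh()))
  s_all <- mk(1:5)
  singles <- lapply(1:5, function(i) mk(i))
  amp_sum <- sum(vapply(singles, junction_amplitude, 0))
  expect_equal(junction_amplitude(s_all), amp_sum, tolerance = 1e-9)
  probe <- rbind(c(20, 10, 5))
  inc_all <- eval_conc(s_all, probe, "cyto") - nM_to_molm3(30)
  inc_sum <- sum(vapply(singles, function(s)
    eval_conc(s, probe, "cyto") - nM_to_molm3(30), 0))
  expect_equal(inc_all, inc_sum, tolerance = 1e-9)
})

test_that("solver matches the half-space Green's function on a flat PM", {
  s <- sol_flat()
  Q <- s$Q_orai[1]
  for (r in c(10, 20, 30, 40, 50)) {
    num <- molm3_to_nM(eval_conc(s, cbind(r, 0, 0), "cyto"))
    ora <- point_source_conc(Q, 220, r, 30)
    expect_lt(abs(num / ora - 1), 0.05)
  }
  expect_lt(s$conservation$rel_err, 0.01)
})

test_that("gating fixed point: rest, local depletion, fast ER diffusion", {
  g <- geom_default()
  # all receptors closed: every ORAI settles at 21% in one iteration
  s_closed <- solve_steady(scenario(
    g, layout_full(), open_orai = 1:5, open_ip3r = integer(0),
    orai_gated_by_sensing = TRUE, mesh = coarse_mesh()))
  expect_equal(s_closed$f, rep(0.21, 5))
  expect_equal(s_closed$gating_iterations, 1L)
  # one receptor open at slow ER diffusion: its sensing ORAI half-opens
  s10 <- sol_ip3r1()
  map <- attr(layout_full(), "orai_to_ip3r")
  sensing_orai <- which(map == 1)
  expect_equal(s10$f[sensing_orai], 0.5)
  expect_equal(s10$f[-sensing_orai], rep(0.21, 4))
  expect_lt(sensing_average(s10, 1), 360)
  f_direct <- gating_fixed_point(s10$scenario)
  expect_equal(as.numeric(f_direct), s10$f)
  expect_equal(attr(f_direct, "sensed_uM")[1], sensing_average(s10, 1))
  # fast ER diffusion: replenishment keeps every channel minimal
  s110 <- sol_ip3r1_fast()
  expect_equal(s110$f, rep(0.21, 5))
  expect_gte(sensing_average(s110, 1), 360)
  # the sensed depletion shrinks and the release flux grows with D_S
  expect_lt(400 - sensing_average(s110, 1), 400 - sensing_average(s10, 1))
  expect_gt(s110$Q_ip3r[1], s10$Q_ip3r[1])
})

test_that("transient: fast plateau, collapse on closure, inert zero window", {
  g <- geom_default()
  scn <- scenario(g, layout_orai_only(), open_orai = 1:5,
                  mode = "transient", event_window = c(0, 0.044),
                  snapshot_times = 0.022, mesh = coarse_mesh())
  tr <- solve_transient(scn, dt = 5e-4)
  i22 <- which.min(abs(tr$times - 0.022))
  expect_lt(abs(tr$amplitude[i22] / tr$steady_amplitude - 1), 0.02)
  i2 <- which.min(abs(tr$times - 0.002))
  expect_gt(tr$amplitude[i2] / tr$amplitude[i22], 0.95)  # plateau in a few ms
  iend <- which.min(abs(tr$times - (0.044 + 0.005)))
  expect_lt(tr$amplitude[iend] / tr$amplitude[i22], 0.05) # rapid collapse
  expect_length(tr$snapshots, 1)
  # spread-source plateau agrees with the singularity-subtraction solver
  expect_lt(abs(molm3_to_nM(tr$steady_amplitude) /
                  junction_amplitude(sol_orai5()) - 1), 0.02)
  # zero-length event window: fields remain at the initial conditions
  scn0 <- scenario(g, layout_orai_only(), open_orai = 1:5,
                   mode = "transient", event_window = c(0, 0),
                   snapshot_times = numeric(0), mesh = coarse_mesh())
  tr0 <- solve_transient(scn0, dt = 5e-4, t_end = 0.004)
  expect_lt(max(abs(tr0$amplitude)), 1e-15)
})

test_that("refinement leaves a uniform field unchanged", {
  g <- geom_default()
  scn <- scenario(g, layout_full(), mesh = coarse_mesh())
  cs <- convergence_study(scn, levels = 2)
  expect_equal(cs$amplitude_nM, c(0, 0), tolerance = 1e-12)
})

test_that("scenario validation", {
  g <- geom_default()
  expect_error(scenario(g, layout_orai_only(), open_orai = 9),
               class = "socesim_invalid_argument")
  expect_error(scenario(g, layout_orai_only(), open_ip3r = 1),
               class = "socesim_invalid_argument")
  expect_error(scenario(g, layout_orai_only(), orai_gated_by_sensing = TRUE),
               class = "socesim_invalid_argument")
  expect_error(scenario(g, layout_full(), event_window = c(1, 0)),
               class = "socesim_invalid_argument")
})
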