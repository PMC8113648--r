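test_that("presets resolve to valid scenarios", {
  for (nm in scenario_presets()) {
    scn <- preset_scenario(nm, n_open = 1, mesh = coarse_mesh())
    expect_s3_class(scn, "scenario")
  }
  s9n <- preset_scenario("fig9", variant = "nearest", mesh = coarse_mesh())
  s9f <- preset_scenario("fig9", variant = "furthest", mesh = coarse_mesh())
  expect_length(s9n$open_ip3r, 4)
  expect_length(s9f$open_ip3r, 4)
  expect_false(setequal(s9n$open_ip3r, s9f$open_ip3r))
  expect_error(preset_scenario("does-not-exist"),
               class = "socesim_usage_error")
})

test_that("clustered ORAI spacing maps to the right ring radius", {
  scn <- preset_scenario("fig8", n_open = 1, orai_spacing = 37.7,
                         mesh = coarse_mesh())
  orai <- Filter(function(p) p$kind == "ORAI", unclass(scn$layout))
  r <- sqrt(sum(orai[[1]]$center[1:2]^2))
  expect_equal(r, 37.7 / (2 * sin(pi / 5)), tolerance = 1e-12)
  expect_equal(r, 32.07, tolerance = 1e-3)
  expect_equal(attr(ring_positions(5, r), "spacing"), 37.7,
               tolerance = 1e-12)
})

test_that("amplitude sweeps increase with the number of open channels", {
  tab <- sweep_scenarios("fig2", "n_open", 1:5, mesh = coarse_mesh())
  expect_equal(nrow(tab), 5)
  expect_true(all(diff(tab$junction_amplitude_nM) > 0))
  expect_true(attr(tab, "monotone_increasing"))
  expect_error(sweep_scenarios("fig2", "n_open", numeric(0)),
               class = "socesim_usage_error")
})

test_that("run_scenario writes a reproducible, re-runnable bundle", {
  dir1 <- tempfile("socesim_t_")
  r <- run_scenario(preset_scenario("fig2", n_open = 3,
                                    mesh = coarse_mesh()),
                    outdir = dir1, label = "fig2_n3")
  for (f in c("observables.csv", "fluxes.csv", "manifest.yaml", "run.log",
              "summary.json"))
    expect_true(file.exists(file.path(dir1, f)))
  # the manifest re-solves to the identical observables (no hidden state)
  scn2 <- read_scenario_config(file.path(dir1, "manifest.yaml"))
  s2 <- solve_steady(scn2)
  expect_equal(junction_amplitude(s2),
               r$observables$junction_amplitude_nM, tolerance = 1e-12)
  js <- jsonlite::read_json(file.path(dir1, "summary.json"))
  expect_equal(js$n_orai_open, 3)
  # re-export is byte-identical
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  export_run(r$solution, "csv", p1)
  export_run(r$solution, "csv", p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the shipped example config parses and solves", {
  cfg <- system.file("extdata", "example_scenario.yaml", package = "socesim")
  scn <- read_scenario_config(cfg)
  expect_identical(scn$open_ip3r, c(1L, 2L))
  expect_true(scn$orai_gated_by_sensing)
  expect_equal(scn$event_window, c(0, 0.044))
  s <- solve_steady(scn)
  expect_gt(junction_amplitude(s), 0)
  expect_true(any(s$f == 0.5))  # depletion around the open pair gates ORAI
})

test_that("config validation reports unknown fields with their path", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("params:", "  D_S: 10", "  bogus_field: 1"), cfg)
  err <- tryCatch(read_scenario_config(cfg), error = function(e) e)
  expect_s3_class(err, "socesim_usage_error")
  expect_match(conditionMessage(err), "params")
  expect_match(conditionMessage(err), "bogus_field")
  expect_error(read_scenario_config("no/such/file.yaml"),
               class = "socesim_usage_error")
  expect_error(export_run(sol_rest(), "docx", tempfile()),
               class = "socesim_usage_error")
})

test_that("VTK export is structurally valid and complete", {
  path <- tempfile(fileext = ".vtk")
  write_vtk_fields(sol_orai5(), path)
  lines <- readLines(path)
  expect_match(lines[1], "vtk DataFile")
  expect_match(lines[4], "RECTILINEAR_GRID")
  m <- sol_orai5()$mesh
  expect_match(lines[5], sprintf("DIMENSIONS %d %d %d",
                                 m$nx + 1, m$ny + 1, m$nz + 1))
  celldata <- grep("^CELL_DATA", lines, value = TRUE)
  expect_equal(as.integer(sub("CELL_DATA ", "", celldata)), m$ncell)
  expect_length(grep("^SCALARS", lines), 3)
  # every scalar block carries one value per cell
  vals <- as.numeric(unlist(strsplit(
    lines[(grep("LOOKUP_TABLE", lines)[1] + 1):(grep("^SCALARS",
                                                     lines)[2] - 1)], " ")))
  expect_equal(length(vals[!is.na(vals)]), m$ncell)
})
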