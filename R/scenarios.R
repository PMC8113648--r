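# Named scenario presets reproducing the study's simulation series, YAML
# config parsing, run/sweep drivers and output management.

ORAI_DEFAULT_SPACING <- 47    # nm, 5 channels on the 40 nm ring
ORAI_CLUSTERED_SPACING <- 37.7

spacing_to_ring_radius <- function(spacing, n = 5) spacing / (2 * sin(pi / n))

#' Mesh profiles
#'
#' `"default"` is the production resolution used by the presets; `"coarse"`
#' is for quick exploration; `"fine"` for convergence checks.
#'
#' @param profile profile name.
#' @return a [mesh_spec()].
#' @export
mesh_profile <- function(profile = c("default", "coarse", "fine")) {
  switch(match.arg(profile),
         default = mesh_spec(6, 25, refinement_levels = 3),
         coarse = mesh_spec(10, 30, refinement_levels = 2),
         fine = mesh_spec(4, 18, refinement_levels = 2))
}

#' Available scenario presets
#'
#' @return character vector of preset names.
#' @export
scenario_presets <- function() {
  c("fig2", "fig3", "fig4", "fig5", "fig8", "fig9")
}

#' Build a preset scenario
#'
#' * `fig2` -- ORAI1-only junction (no IP3Rs): `n_open` ORAI1 channels open
#'   at the full-ER fraction (21%).
#' * `fig3` -- `n_open` IP3Rs open (ascending index), all five ORAI1 present
#'   and gated by the sensed ER averages; D_S = 10 um^2/s.
#' * `fig4` -- as `fig3` but without ORAI1 channels (release-only control).
#' * `fig5` -- as `fig3` with fast ER diffusion, D_S = 110 um^2/s.
#' * `fig8` -- as `fig3` with clustered ORAI1 channels (37.7 nm spacing).
#' * `fig9` -- SERCA operating points: the 4 IP3Rs nearest (or furthest
#'   from) the reference SERCA pump are opened (`variant`).
#'
#' @param name preset name (see [scenario_presets()]).
#' @param n_open number of open channels of the swept kind.
#' @param D_S ER diffusion coefficient override (um^2/s).
#' @param orai_spacing ORAI1 inter-channel spacing (nm) for `fig8`.
#' @param variant `"nearest"` or `"furthest"` for `fig9`.
#' @param mesh a [mesh_spec()] or profile name.
#' @param params optional [flux_params()] override.
#' @return a [scenario()].
#' @export
preset_scenario <- function(name, n_open = NULL, D_S = NULL,
                            orai_spacing = ORAI_CLUSTERED_SPACING,
                            variant = c("nearest", "furthest"),
                            mesh = "default", params = NULL) {
  if (!name %in% scenario_presets())
    usage_error("unknown preset '%s' (available: %s)", name,
                paste(scenario_presets(), collapse = ", "))
  if (is.character(mesh)) mesh <- mesh_profile(mesh)
  g <- junction_geometry()
  mk_params <- function(ds_default) {
    if (!is.null(params)) return(params)
    flux_params(D_S = if (is.null(D_S)) ds_default else D_S)
  }
  switch(name,
    fig2 = {
      n <- if (is.null(n_open)) 5L else as.integer(n_open)
      scenario(g, channel_layout(g, n_ip3r = 0), mk_params(10),
               open_orai = seq_len(n), mesh = mesh)
    },
    fig3 = {
      n <- if (is.null(n_open)) 1L else as.integer(n_open)
      scenario(g, channel_layout(g), mk_params(10),
               open_orai = 1:5, open_ip3r = seq_len(n),
               orai_gated_by_sensing = TRUE, mesh = mesh)
    },
    fig4 = {
      n <- if (is.null(n_open)) 1L else as.integer(n_open)
      scenario(g, channel_layout(g, n_orai = 0), mk_params(10),
               open_ip3r = seq_len(n), mesh = mesh)
    },
    fig5 = {
      n <- if (is.null(n_open)) 1L else as.integer(n_open)
      scenario(g, channel_layout(g), mk_params(110),
               open_orai = 1:5, open_ip3r = seq_len(n),
               orai_gated_by_sensing = TRUE, mesh = mesh)
    },
    fig8 = {
      n <- if (is.null(n_open)) 1L else as.integer(n_open)
      lay <- channel_layout(
        g, orai_ring_radius = spacing_to_ring_radius(orai_spacing))
      scenario(g, lay, mk_params(10), open_orai = 1:5,
               open_ip3r = seq_len(n), orai_gated_by_sensing = TRUE,
               mesh = mesh)
    },
    fig9 = {
      variant <- match.arg(variant)
      lay <- channel_layout(g)
      ref <- patches_of(lay, "SERCA")[[1]]$center
      ip3r <- patches_of(lay, "IP3R")
      d <- vapply(ip3r, function(p) sqrt(sum((p$center - ref)^2)), 0)
      sel <- order(d, decreasing = (variant == "furthest"))[1:4]
      scenario(g, lay, mk_params(10), open_orai = 1:5,
               open_ip3r = sort(sel), orai_gated_by_sensing = TRUE,
               mesh = mesh)
    })
}

# --- YAML configs -----------------------------------------------------------

config_take <- function(cfg, section, builder, path) {
  sub <- cfg[[section]]
  if (is.null(sub)) return(builder())
  ok <- names(formals(builder))
  bad <- setdiff(names(sub), ok)
  if (length(bad))
    usage_error("config error at %s.%s: unknown field(s) %s",
                path, section, paste(bad, collapse = ", "))
  do.call(builder, sub)
}

#' Read a scenario from a YAML config file
#'
#' Sections `geometry`, `layout`, `params`, `gating`, `mesh` take the
#' arguments of the corresponding constructors; section `scenario` takes
#' `open_orai`, `open_ip3r`, `orai_gated_by_sensing`, `orai_f`, `mode`,
#' `event_window_ms` and `snapshot_times_ms`.  Unknown fields are reported
#' with their path.
#'
#' @param path YAML file.
#' @return a [scenario()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) usage_error("config file '%s' does not exist", path)
  cfg <- yaml::read_yaml(path)
  geom <- config_take(cfg, "geometry", junction_geometry, path)
  params <- config_take(cfg, "params", flux_params, path)
  gating <- config_take(cfg, "gating", gating_table, path)
  mesh <- config_take(cfg, "mesh", mesh_spec, path)
  lay_args <- cfg$layout %||% list()
  bad <- setdiff(names(lay_args), names(formals(channel_layout))[-1])
  if (length(bad))
    usage_error("config error at %s.layout: unknown field(s) %s",
                path, paste(bad, collapse = ", "))
  layout <- do.call(channel_layout, c(list(geom), lay_args))
  sc <- cfg$scenario
  if (is.null(sc)) sc <- list()
  known <- c("open_orai", "open_ip3r", "orai_gated_by_sensing", "orai_f",
             "mode", "event_window_ms", "snapshot_times_ms")
  bad <- setdiff(names(sc), known)
  if (length(bad))
    usage_error("config error at %s.scenario: unknown field(s) %s",
                path, paste(bad, collapse = ", "))
  scenario(geom, layout, params, gating,
           open_orai = unlist(sc$open_orai) %||% integer(0),
           open_ip3r = unlist(sc$open_ip3r) %||% integer(0),
           orai_gated_by_sensing = sc$orai_gated_by_sensing %||% FALSE,
           orai_f = sc$orai_f,
           event_window = (unlist(sc$event_window_ms) %||% c(0, 44)) / 1e3,
           snapshot_times = (unlist(sc$snapshot_times_ms) %||% 22) / 1e3,
           mode = sc$mode %||% "steady",
           mesh = mesh)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the fully resolved configuration of a scenario
#'
#' @param scn a [scenario()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scn, path) {
  g <- scn$geometry; p <- scn$params
  cfg <- list(
    geometry = g[c("box_side", "gap", "junction_radius", "cone_top_radius",
                   "cone_bottom_radius", "cone_depth")],
    layout = attr(scn$layout, "args"),
    params = p[c("I_ORAI", "I_IP3R", "C_S0", "C_C0", "D_C", "D_S",
                 "serca_Vmax", "serca_KC")],
    gating = scn$gating[c("thresholds", "fractions")],
    scenario = list(mode = scn$mode,
                    open_orai = scn$open_orai, open_ip3r = scn$open_ip3r,
                    orai_gated_by_sensing = scn$orai_gated_by_sensing,
                    event_window_ms = scn$event_window * 1e3,
                    snapshot_times_ms = scn$snapshot_times * 1e3),
    mesh = scn$mesh[c("target_h_patch", "target_h_bulk")])
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# --- run / sweep / export ---------------------------------------------------

#' Run a scenario and write its outputs
#'
#' Accepts a preset name, a YAML config path or a [scenario()] object;
#' solves it and writes `observables.csv`, `fluxes.csv`, `manifest.yaml`,
#' `summary.json` and `run.log` (plus `fields.vtk` on request) to `outdir`.
#'
#' @param x preset name, config path, or [scenario()].
#' @param outdir output directory (created if needed).
#' @param n_open,D_S,variant,mesh passed to [preset_scenario()] when `x` is
#'   a preset name.
#' @param theta optional spatial-extent threshold (nM).
#' @param export_fields write `fields.vtk`.
#' @param label scenario label in the observables row.
#' @return invisibly, a list with the solution, observables and `outdir`.
#' @export
run_scenario <- function(x, outdir = tempfile("socesim_run_"),
                         n_open = NULL, D_S = NULL,
                         variant = "nearest", mesh = "default",
                         theta = NULL, export_fields = FALSE,
                         label = NULL) {
  scn <- if (inherits(x, "scenario")) x
    else if (is.character(x) && x %in% scenario_presets())
      preset_scenario(x, n_open = n_open, D_S = D_S, variant = variant,
                      mesh = mesh)
    else if (is.character(x) && file.exists(x)) read_scenario_config(x)
    else usage_error("'%s' is neither a preset nor an existing config file",
                     as.character(x)[1])
  if (is.null(label))
    label <- if (is.character(x)) basename(x) else "scenario"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  logline("socesim run: %s (mode %s)", label, scn$mode)
  t0 <- proc.time()[3]
  if (scn$mode == "steady") {
    sol <- solve_steady(scn)
    obs <- observable_set(sol, theta = theta, label = label)
    logline("solved in %.1f s; %d gating / %d flux iterations",
            proc.time()[3] - t0, sol$gating_iterations,
            sol$picard_iterations)
    logline("cytosol flux balance rel. err. %.2e", sol$conservation$rel_err)
    utils::write.csv(obs, file.path(outdir, "observables.csv"),
                     row.names = FALSE)
    utils::write.csv(sol$flux_report, file.path(outdir, "fluxes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(obs), file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    if (export_fields) write_vtk_fields(sol, file.path(outdir, "fields.vtk"))
  } else {
    sol <- solve_transient(scn)
    obs <- data.frame(scenario = label,
                      plateau_amplitude_nM =
                        molm3_to_nM(max(sol$amplitude)),
                      steady_amplitude_nM =
                        molm3_to_nM(sol$steady_amplitude))
    utils::write.csv(
      data.frame(time_ms = sol$times * 1e3,
                 amplitude_nM = molm3_to_nM(sol$amplitude)),
      file.path(outdir, "amplitude_timeseries.csv"), row.names = FALSE)
    utils::write.csv(obs, file.path(outdir, "observables.csv"),
                     row.names = FALSE)
    logline("transient solved in %.1f s (%d steps)",
            proc.time()[3] - t0, length(sol$times))
  }
  write_scenario_config(scn, file.path(outdir, "manifest.yaml"))
  invisible(list(solution = sol, observables = obs, outdir = outdir))
}

#' Sweep a preset over a variable
#'
#' One observables row per value; supported variables: `n_open` (open
#' channel count of the preset's swept kind), `D_S` (ER diffusivity,
#' um^2/s) and `orai_spacing` (nm, `fig8`).
#'
#' @param preset preset name.
#' @param variable swept variable.
#' @param values numeric vector of values.
#' @param mesh mesh profile or [mesh_spec()].
#' @param theta optional spatial-extent threshold (nM).
#' @return data frame of observables, one row per value.
#' @export
sweep_scenarios <- function(preset,
                            variable = c("n_open", "D_S", "orai_spacing"),
                            values, mesh = "default", theta = NULL) {
  variable <- match.arg(variable)
  if (!length(values)) usage_error("empty sweep value list")
  rows <- lapply(values, function(v) {
    scn <- switch(variable,
      n_open = preset_scenario(preset, n_open = v, mesh = mesh),
      D_S = preset_scenario(preset, D_S = v, mesh = mesh),
      orai_spacing = preset_scenario(preset, orai_spacing = v, mesh = mesh))
    sol <- solve_steady(scn)
    cbind(observable_set(sol, theta = theta,
                         label = sprintf("%s_%s=%g", preset, variable, v)),
          value = v)
  })
  out <- do.call(rbind, rows)
  attr(out, "monotone_increasing") <-
    !is.unsorted(out$junction_amplitude_nM, strictly = FALSE)
  out
}

#' Export a solved scenario in a standard format
#'
#' @param run a [run_scenario()] result (or a solution object).
#' @param format `"vtk"` (rectilinear-grid field file), `"csv"`
#'   (observables) or `"png"` (mid-plane cross-section).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_run <- function(run, format = c("vtk", "csv", "png"), path) {
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       usage_error("unsupported export format '%s'",
                                   as.character(format)[1]))
  sol <- if (inherits(run, "junction_solution")) run else run$solution
  switch(format,
    vtk = write_vtk_fields(sol, path),
    csv = {
      obs <- if (inherits(run, "junction_solution"))
        observable_set(run) else run$observables
      utils::write.csv(obs, path, row.names = FALSE)
      invisible(path)
    },
    png = export_cross_section_png(cross_section(sol), path))
}
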