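# Steady and transient solution of the coupled cytosol/ER diffusion problem.
#
# Steady state: for each sub-domain the total field is decomposed as
# C = C_ref + sum_p u_p + w, where u_p = (s_p Q_p) / (2 pi D r) is the
# half-space kernel of patch p (s_p the sign of its rate into the domain)
# and w solves the geometry-only operator with compensation data (see
# mesh.R).  Patch molar rates that depend on mouth concentrations (IP3R,
# SERCA) are converged by Picard iteration with a semi-implicit update for
# the IP3R self-term; the discrete ORAI open fractions are converged by an
# outer fixed-point loop on the sensed ER averages.

#' Simulation scenario
#'
#' @param geometry a [junction_geometry()].
#' @param layout a [channel_layout()].
#' @param params a [flux_params()].
#' @param gating a [gating_table()].
#' @param open_orai indices of ORAI1 channels open during the event window.
#' @param open_ip3r indices of IP3 receptors open during the event window.
#' @param orai_gated_by_sensing if `TRUE` the open fraction of each open
#'   ORAI1 follows the sensed ER average around its associated IP3R; if
#'   `FALSE` all open ORAI1 use the full-ER fraction (or `orai_f`).
#' @param orai_f optional fixed open fraction overriding the gating table.
#' @param event_window numeric length-2, channel opening interval (s).
#' @param snapshot_times times (s) at which transient fields are stored.
#' @param mode `"steady"` or `"transient"`.
#' @param mesh a [mesh_spec()].
#' @return An object of class `scenario`.
#' @export
scenario <- function(geometry = junction_geometry(),
                     layout = channel_layout(geometry),
                     params = flux_params(),
                     gating = gating_table(),
                     open_orai = integer(0), open_ip3r = integer(0),
                     orai_gated_by_sensing = FALSE, orai_f = NULL,
                     event_window = c(0, 0.044),
                     snapshot_times = 0.022,
                     mode = c("steady", "transient"),
                     mesh = mesh_spec()) {
  mode <- match.arg(mode)
  n_orai <- length(patches_of(layout, "ORAI"))
  n_ip3r <- length(patches_of(layout, "IP3R"))
  if (length(open_orai) && (min(open_orai) < 1 || max(open_orai) > n_orai))
    invalid_argument("open_orai references channels outside 1..%d", n_orai)
  if (length(open_ip3r) && (min(open_ip3r) < 1 || max(open_ip3r) > n_ip3r))
    invalid_argument("open_ip3r references receptors outside 1..%d", n_ip3r)
  if (diff(event_window) < 0)
    invalid_argument("event_window must be non-decreasing")
  if (orai_gated_by_sensing && n_ip3r == 0)
    invalid_argument("sensed gating requires IP3Rs in the layout")
  structure(list(geometry = geometry, layout = layout, params = params,
                 gating = gating,
                 open_orai = as.integer(open_orai),
                 open_ip3r = as.integer(open_ip3r),
                 orai_gated_by_sensing = orai_gated_by_sensing,
                 orai_f = orai_f,
                 event_window = event_window,
                 snapshot_times = snapshot_times,
                 mode = mode, mesh = mesh),
            class = "scenario")
}

# domain diffusivity and reference concentration
dom_D <- function(params, domain) if (domain == "cyto") params$dc else params$ds
dom_ref <- function(params, domain) if (domain == "cyto") params$cc0 else params$cs0

# per-side signed rates from the per-patch rate vectors
side_rates <- function(m, Q_orai, Q_ip3r, R_serca) {
  vapply(m$sides, function(s) {
    q <- switch(s$kind, ORAI = Q_orai[s$index], IP3R = Q_ip3r[s$index],
                SERCA = R_serca[s$index])
    s$sgn * q
  }, 0)
}

solve_w <- function(m, params, sq) {
  out <- list()
  for (d in c("cyto", "er")) {
    idx <- m[[paste0("sides_", d)]]
    ndof <- length(m$cells[[d]])
    rhs <- numeric(ndof)
    for (si in idx) {
      s <- m$sides[[si]]
      if (sq[si] != 0) rhs[s$bidx] <- rhs[s$bidx] + sq[si] * s$bval
    }
    f <- mesh_factor(m, d)
    out[[d]] <- if (all(rhs == 0)) numeric(ndof)
      else as.numeric(Matrix::solve(f, rhs)) / dom_D(params, d)
  }
  out
}

# concentration terms at a side's patch point: environment (cross kernels +
# smooth remainder, excluding the side's own self term) and the self
# coefficients; all in mol/m^3
side_env <- function(m, params, d, si_local, sq, w) {
  idx <- m[[paste0("sides_", d)]]
  D <- dom_D(params, d)
  G <- m[[paste0("G_", d)]]
  s <- m$sides[[idx[si_local]]]
  cross <- if (length(idx) > 1)
    sum(sq[idx] * G[si_local, ] / D) else 0
  dom_ref(params, d) + cross + w[[d]][s$eval_cell]
}

local_side_of <- function(m, d, kind, index) {
  idx <- m[[paste0("sides_", d)]]
  which(vapply(m$sides[idx], function(s)
    s$kind == kind && s$index == index, TRUE))
}

# sensed ER average around each IP3R (mol/m^3)
sensed_averages <- function(m, params, sq, w) {
  n <- length(m$cubes)
  if (n == 0) return(numeric(0))
  idx_er <- m$sides_er
  vapply(seq_len(n), function(i) {
    cb <- m$cubes[[i]]
    analytic <- sum(sq[idx_er] * cb$g / params$ds)
    params$cs0 + analytic + sum(w$er[cb$cells] * cb$w)
  }, 0)
}

#' Steady-state solution of a scenario
#'
#' Converges the patch molar rates (Picard, semi-implicit IP3R self-term)
#' and, when `orai_gated_by_sensing` is set, the discrete ORAI open-fraction
#' assignment (outer fixed point; a two-cycle oscillation is resolved by
#' taking the smaller open fraction per channel).
#'
#' @param scn a [scenario()].
#' @param mesh optional prebuilt [build_geometry()] mesh.
#' @param quiet suppress progress messages.
#' @return An object of class `junction_solution`.
#' @export
solve_steady <- function(scn, mesh = NULL, quiet = TRUE) {
  if (scn$mode != "steady") invalid_argument("scenario mode must be 'steady'")
  m <- if (is.null(mesh)) build_geometry(scn$geometry, scn$layout, scn$mesh)
       else mesh
  p <- scn$params
  n_orai <- length(patches_of(scn$layout, "ORAI"))
  n_ip3r <- length(patches_of(scn$layout, "IP3R"))
  n_serca <- length(patches_of(scn$layout, "SERCA"))
  map <- attr(scn$layout, "orai_to_ip3r")
  f_rest <- orai_open_fraction(scn$gating, p$C_S0)

  f_of <- function(sensed) {
    f <- numeric(n_orai)
    if (!length(scn$open_orai)) return(f)
    if (!is.null(scn$orai_f)) { f[scn$open_orai] <- scn$orai_f; return(f) }
    if (!scn$orai_gated_by_sensing) { f[scn$open_orai] <- f_rest; return(f) }
    f[scn$open_orai] <- orai_open_fraction(
      scn$gating, molm3_to_uM(sensed[map[scn$open_orai]]))
    f
  }

  alpha <- p$I_IP3R / (p$z * p$F) / (p$cs0 - p$cc0)

  picard <- function(f_orai) {
    Q_orai <- orai_molar_rate(f_orai, p)
    Q_ip3r <- numeric(max(n_ip3r, 1))
    R_serca <- numeric(max(n_serca, 1))
    w <- list(cyto = numeric(length(m$cells$cyto)),
              er = numeric(length(m$cells$er)))
    sq <- side_rates(m, Q_orai, Q_ip3r, R_serca)
    relax <- 0.7
    for (it in 1:80) {
      Q_old <- c(Q_ip3r, R_serca)
      # IP3R rates: semi-implicit in the disc self-terms on both faces
      for (i in scn$open_ip3r) {
        lc <- local_side_of(m, "cyto", "IP3R", i)
        le <- local_side_of(m, "er", "IP3R", i)
        s_c <- m$sides[[m$sides_cyto[lc]]]
        s_e <- m$sides[[m$sides_er[le]]]
        cs_env <- side_env(m, p, "er", le, sq, w)
        cc_env <- side_env(m, p, "cyto", lc, sq, w)
        kS <- s_e$coef_avg / p$ds
        kC <- s_c$coef_avg / p$dc
        Qn <- alpha * (cs_env - cc_env) / (1 + alpha * (kS + kC))
        Q_ip3r[i] <- relax * Qn + (1 - relax) * Q_ip3r[i]
      }
      # SERCA rates from the (lagged) mouth averages
      for (i in seq_len(n_serca)) {
        lc <- local_side_of(m, "cyto", "SERCA", i)
        le <- local_side_of(m, "er", "SERCA", i)
        s_c <- m$sides[[m$sides_cyto[lc]]]
        s_e <- m$sides[[m$sides_er[le]]]
        cc <- side_env(m, p, "cyto", lc, sq, w) -
          R_serca[i] * s_c$coef_avg / p$dc
        cs <- side_env(m, p, "er", le, sq, w) +
          R_serca[i] * s_e$coef_avg / p$ds
        Rn <- serca_molar_rate(molm3_to_uM(max(cc, 0)),
                               molm3_to_uM(max(cs, 0)), p)
        R_serca[i] <- relax * Rn + (1 - relax) * R_serca[i]
      }
      sq <- side_rates(m, Q_orai, Q_ip3r, R_serca)
      w <- solve_w(m, p, sq)
      dq <- max(abs(c(Q_ip3r, R_serca) - Q_old))
      scale <- max(abs(c(Q_orai, Q_ip3r, R_serca, 1e-30)))
      if (dq <= 1e-8 * scale) break
      if (it == 80) solver_failure("flux Picard iteration did not converge")
    }
    list(Q_orai = Q_orai, Q_ip3r = Q_ip3r, R_serca = R_serca,
         sq = sq, w = w, iterations = it)
  }

  # outer discrete gating fixed point
  f_hist <- list()
  f <- f_of(rep(p$cs0, max(n_ip3r, 1)))
  state <- NULL
  gate_it <- 0L
  repeat {
    gate_it <- gate_it + 1L
    state <- picard(f)
    sensed <- sensed_averages(m, p, state$sq, state$w)
    f_new <- f_of(sensed)
    if (identical(f_new, f)) break
    if (length(f_hist) >= 1 &&
        identical(f_new, f_hist[[length(f_hist)]])) {
      # 2-cycle: choose the smaller open fraction per channel (conservative)
      f <- pmin(f_new, f)
      state <- picard(f)
      sensed <- sensed_averages(m, p, state$sq, state$w)
      break
    }
    f_hist[[length(f_hist) + 1]] <- f
    f <- f_new
    if (gate_it >= 20)
      solver_failure("gating fixed point did not stabilise in 20 iterations")
  }

  sol <- structure(list(
    mesh = m, scenario = scn, params = p,
    f = f, Q_orai = state$Q_orai, Q_ip3r = state$Q_ip3r,
    R_serca = state$R_serca, sq = state$sq, w = state$w,
    sensed = sensed, gating_iterations = gate_it,
    picard_iterations = state$iterations), class = "junction_solution")
  sol$flux_report <- flux_report(sol)
  sol$conservation <- conservation_report(sol)
  sol
}

#' Realised ORAI1 open fractions of a sensed-gating scenario
#'
#' Runs the steady solve with its self-consistent discrete gating loop and
#' returns the converged open fraction per ORAI1 channel, with the sensed
#' ER averages (uM) attached.
#'
#' @param scn a [scenario()] with `orai_gated_by_sensing = TRUE`.
#' @return numeric vector of open fractions, attribute `sensed_uM`.
#' @export
gating_fixed_point <- function(scn) {
  if (!scn$orai_gated_by_sensing)
    invalid_argument("scenario does not use sensed gating")
  sol <- solve_steady(scn)
  structure(sol$f, sensed_uM = molm3_to_uM(sol$sensed))
}

#' @export
print.junction_solution <- function(x, ...) {
  cat(sprintf("junction_solution: %d gating / %d flux iterations\n",
              x$gating_iterations, x$picard_iterations))
  cat(sprintf("  ORAI open fractions: %s\n",
              paste(format(x$f, digits = 3), collapse = " ")))
  cat(sprintf("  cytosol flux balance rel. err.: %.2e\n",
              x$conservation$rel_err))
  invisible(x)
}

# mouth concentrations of one patch side (mol/m^3); `which` selects the
# disc-average (flux convention) or the centre (peak) value
side_mouth <- function(sol, d, kind, index, which = c("avg", "center")) {
  which <- match.arg(which)
  m <- sol$mesh
  l <- local_side_of(m, d, kind, index)
  if (!length(l)) return(NA_real_)
  s <- m$sides[[m[[paste0("sides_", d)]][l]]]
  env <- side_env(m, sol$params, d, l, sol$sq, sol$w)
  gl <- m[[paste0("sides_", d)]][l]
  coef <- if (which == "avg") s$coef_avg else s$coef_center
  env + sol$sq[gl] * coef / dom_D(sol$params, d)
}

flux_report <- function(sol) {
  scn <- sol$scenario
  rows <- list()
  for (pch in scn$layout) {
    k <- pch$kind; i <- pch$index
    open <- switch(k,
      ORAI = i %in% scn$open_orai,
      IP3R = i %in% scn$open_ip3r,
      SERCA = TRUE)
    Q <- switch(k, ORAI = sol$Q_orai[i], IP3R = sol$Q_ip3r[i],
                SERCA = sol$R_serca[i])
    rows[[length(rows) + 1]] <- data.frame(
      kind = k, index = i, open = open,
      f = if (k == "ORAI") sol$f[i] else NA_real_,
      molar_rate = Q,
      cc_mouth_uM = molm3_to_uM(side_mouth(sol, "cyto", k, i)),
      cs_mouth_uM = if (k == "ORAI") NA_real_
                    else molm3_to_uM(side_mouth(sol, "er", k, i)),
      sensed_uM = if (k == "IP3R" && length(sol$sensed) >= i)
        molm3_to_uM(sol$sensed[i]) else NA_real_)
  }
  do.call(rbind, rows)
}

# Dirichlet-boundary molar outflow of the total field for one domain
dirichlet_outflow <- function(sol, d) {
  m <- sol$mesh
  p <- sol$params
  bfd <- m$bf[[d]]
  dirf <- which(bfd$type == "dirichlet")
  if (!length(dirf)) return(0)
  idx <- m[[paste0("sides_", d)]]
  D <- dom_D(p, d)
  out_u <- 0
  wb <- numeric(length(dirf))
  for (si in idx) {
    s <- m$sides[[si]]
    out_u <- out_u + sol$sq[si] * s$phi_dir
    wb <- wb - (sol$sq[si] / D) * s$gdir
  }
  wcell <- sol$w[[d]][bfd$cell[dirf]]
  out_w <- sum(D * bfd$Tb[dirf] * (wcell - wb))
  out_u + out_w
}

conservation_report <- function(sol) {
  in_cyto <- sum(sol$Q_orai) + sum(sol$Q_ip3r) - sum(sol$R_serca)
  gross <- sum(sol$Q_orai) + sum(pmax(sol$Q_ip3r, 0))
  out_c <- dirichlet_outflow(sol, "cyto")
  out_e <- dirichlet_outflow(sol, "er")
  in_er <- -sum(sol$Q_ip3r) + sum(sol$R_serca)
  list(influx_cyto = in_cyto, outflow_cyto = out_c,
       influx_er = in_er, outflow_er = out_e,
       gross_influx = gross,
       rel_err = if (gross > 0) abs(in_cyto - out_c) / gross else 0,
       rel_err_er = if (gross > 0) abs(in_er - out_e) / gross else 0)
}

# nearest-cell index of points (n x 3, nm) in a domain; NA outside
locate_cells <- function(m, points, domain) {
  points <- rbind(points)
  i <- pmin(pmax(findInterval(points[, 1], m$xs, all.inside = TRUE), 1), m$nx)
  j <- pmin(pmax(findInterval(points[, 2], m$ys, all.inside = TRUE), 1), m$ny)
  k <- pmin(pmax(findInterval(points[, 3], m$zs, all.inside = TRUE), 1), m$nz)
  gid <- i + m$nx * (j - 1) + m$nx * m$ny * (k - 1)
  want <- if (domain == "cyto") 1L else 2L
  loc <- ifelse(m$dom[gid] == want, m$glob2loc[gid], NA_integer_)
  loc
}

#' Evaluate a solved concentration field at points
#'
#' Total concentration (analytic kernels plus smooth remainder) at arbitrary
#' points of one sub-domain; points outside the sub-domain give `NA`.
#'
#' @param sol a [solve_steady()] solution.
#' @param points n x 3 matrix of coordinates (nm).
#' @param domain `"cyto"` or `"er"`.
#' @return concentrations (mol/m^3).
#' @export
eval_conc <- function(sol, points, domain = c("cyto", "er")) {
  domain <- match.arg(domain)
  m <- sol$mesh
  p <- sol$params
  points <- rbind(points)
  loc <- locate_cells(m, points, domain)
  out <- rep(NA_real_, nrow(points))
  ok <- !is.na(loc)
  if (!any(ok)) return(out)
  D <- dom_D(p, domain)
  val <- rep(dom_ref(p, domain), sum(ok)) + sol$w[[domain]][loc[ok]]
  ptm <- points[ok, , drop = FALSE] * NM
  for (si in m[[paste0("sides_", domain)]]) {
    s <- m$sides[[si]]
    if (sol$sq[si] == 0) next
    r <- sqrt((ptm[, 1] - s$point[1])^2 + (ptm[, 2] - s$point[2])^2 +
                (ptm[, 3] - s$point[3])^2)
    val <- val + sol$sq[si] / (2 * pi * D * pmax(r, s$a / 2))
  }
  out[ok] <- val
  out
}

# --- transient --------------------------------------------------------------

#' Transient solution of a scenario
#'
#' Implicit-Euler time stepping of the full coupled fields on the same grid,
#' with patch fluxes spread over the membrane faces of each patch footprint.
#' Channels carry flux only inside the scenario's event window; gating (if
#' enabled) is updated quasi-statically each step from the sensed averages.
#'
#' @param scn a [scenario()] with `mode = "transient"`.
#' @param dt time step (s).
#' @param t_end final time (s); defaults to 10 ms past the event window.
#' @param mesh optional prebuilt mesh.
#' @return An object of class `junction_transient` with the amplitude time
#'   series, snapshots at `snapshot_times`, the realised open fractions and
#'   the steady-limit amplitude of the same discretisation.
#' @export
solve_transient <- function(scn, dt = 5e-4, t_end = NULL, mesh = NULL) {
  if (scn$mode != "transient")
    invalid_argument("scenario mode must be 'transient'")
  m <- if (is.null(mesh)) build_geometry(scn$geometry, scn$layout, scn$mesh)
       else mesh
  p <- scn$params
  if (is.null(t_end)) t_end <- scn$event_window[2] + 0.010
  n_steps <- max(1L, ceiling(t_end / dt))
  n_orai <- length(patches_of(scn$layout, "ORAI"))
  n_ip3r <- length(patches_of(scn$layout, "IP3R"))
  n_serca <- length(patches_of(scn$layout, "SERCA"))
  map <- attr(scn$layout, "orai_to_ip3r")
  f_rest <- orai_open_fraction(scn$gating, p$C_S0)
  alpha <- p$I_IP3R / (p$z * p$F) / (p$cs0 - p$cc0)

  fac <- list(); dirr <- list(); cc <- list()
  for (d in c("cyto", "er")) {
    D <- dom_D(p, d)
    M <- Matrix::Diagonal(x = m$vol[[d]] / dt) + D * m$K[[d]]
    fac[[d]] <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE,
                                 super = TRUE)
    bfd <- m$bf[[d]]
    dirf <- which(bfd$type == "dirichlet")
    rr <- numeric(length(m$cells[[d]]))
    if (length(dirf)) {
      agg <- rowsum(D * bfd$Tb[dirf] * dom_ref(p, d), bfd$cell[dirf])
      rr[as.integer(rownames(agg))] <- agg[, 1]
    }
    dirr[[d]] <- rr
    cc[[d]] <- rep(dom_ref(p, d), length(m$cells[[d]]))
  }

  # per-side spread stencils (cells + weights)
  stencil <- lapply(m$sides, function(s) {
    bfd <- m$bf[[s$domain]]
    list(cells = bfd$cell[s$host_rows], w = s$host_w, domain = s$domain,
         sgn = s$sgn)
  })
  cube_cells <- lapply(m$cubes, function(cb) cb)

  sensed_now <- function(cs) {
    vapply(seq_len(length(cube_cells)), function(i)
      sum(cs[cube_cells[[i]]$cells] * cube_cells[[i]]$w), 0)
  }

  times <- seq_len(n_steps) * dt
  amp <- numeric(n_steps)
  fmat <- matrix(0, n_steps, n_orai)
  snaps <- list()
  snap_step <- if (length(scn$snapshot_times))
    vapply(scn$snapshot_times, function(t) which.min(abs(times - t)), 0L)
    else integer(0)

  rate_at <- function(active, ccv, csv, sensed) {
    f <- numeric(n_orai)
    Q_ip <- numeric(max(n_ip3r, 1))
    R_se <- numeric(max(n_serca, 1))
    if (active) {
      if (length(scn$open_orai)) {
        f[scn$open_orai] <- if (!is.null(scn$orai_f)) scn$orai_f
          else if (scn$orai_gated_by_sensing)
            orai_open_fraction(scn$gating,
                               molm3_to_uM(sensed[map[scn$open_orai]]))
          else f_rest
      }
      for (i in scn$open_ip3r) {
        lc <- local_side_of(m, "cyto", "IP3R", i)
        le <- local_side_of(m, "er", "IP3R", i)
        ec <- m$sides[[m$sides_cyto[lc]]]$eval_cell
        ee <- m$sides[[m$sides_er[le]]]$eval_cell
        Q_ip[i] <- alpha * (csv[ee] - ccv[ec])
      }
    }
    for (i in seq_len(n_serca)) {
      lc <- local_side_of(m, "cyto", "SERCA", i)
      le <- local_side_of(m, "er", "SERCA", i)
      ec <- m$sides[[m$sides_cyto[lc]]]$eval_cell
      ee <- m$sides[[m$sides_er[le]]]$eval_cell
      R_se[i] <- serca_molar_rate(molm3_to_uM(max(ccv[ec], 0)),
                                  molm3_to_uM(max(csv[ee], 0)), p)
    }
    list(f = f, Q_orai = orai_molar_rate(f, p), Q_ip3r = Q_ip, R_serca = R_se)
  }

  add_sources <- function(rhs, rates) {
    sqv <- side_rates(m, rates$Q_orai, rates$Q_ip3r, rates$R_serca)
    for (si in seq_along(m$sides)) {
      if (sqv[si] == 0) next
      st <- stencil[[si]]
      rhs[[st$domain]][st$cells] <- rhs[[st$domain]][st$cells] +
        sqv[si] * st$w
    }
    rhs
  }

  last_rates <- NULL
  for (n in seq_len(n_steps)) {
    tmid <- times[n] - dt / 2
    active <- tmid >= scn$event_window[1] && tmid <= scn$event_window[2]
    sensed <- sensed_now(cc$er)
    rates <- rate_at(active, cc$cyto, cc$er, sensed)
    if (active) last_rates <- rates
    rhs <- list(cyto = m$vol$cyto / dt * cc$cyto + dirr$cyto,
                er = m$vol$er / dt * cc$er + dirr$er)
    rhs <- add_sources(rhs, rates)
    cc$cyto <- as.numeric(Matrix::solve(fac$cyto, rhs$cyto))
    cc$er <- as.numeric(Matrix::solve(fac$er, rhs$er))
    amp[n] <- sum(cc$cyto[m$junction$cells] * m$junction$w) - p$cc0
    fmat[n, ] <- rates$f
    if (n %in% snap_step) {
      snaps[[length(snaps) + 1]] <- list(t = times[n], c_cyto = cc$cyto,
                                         c_er = cc$er)
    }
  }

  # steady limit of the same spread-source discretisation, at the last
  # in-window gating state
  steady_amp <- NA_real_
  if (!is.null(last_rates)) {
    rhs0 <- list(cyto = dirr$cyto, er = dirr$er)
    rhs0 <- add_sources(rhs0, last_rates)
    wst <- list()
    for (d in c("cyto", "er")) {
      D <- dom_D(p, d)
      Kf <- mesh_factor(m, d)
      wst[[d]] <- as.numeric(Matrix::solve(Kf, rhs0[[d]] / D))
    }
    steady_amp <- sum(wst$cyto[m$junction$cells] * m$junction$w) - p$cc0
  }

  structure(list(mesh = m, scenario = scn, params = p, dt = dt,
                 times = times, amplitude = amp, f = fmat,
                 snapshots = snaps, steady_amplitude = steady_amp),
            class = "junction_transient")
}

#' Mesh-refinement study of the junction amplitude
#'
#' Re-solves a steady scenario on successively refined grids (spacing scaled
#' by 1/sqrt(2) per level) and reports the junction-average amplitude and the
#' ORAI pore-centre peak per level.  The junction average is the
#' discretisation-robust observable; pore-scale peaks carry their level so
#' their sensitivity is visible.
#'
#' @param scn a steady [scenario()].
#' @param levels number of refinement levels (>= 2).
#' @return data frame with one row per level.
#' @export
convergence_study <- function(scn, levels = 2) {
  if (levels < 2) invalid_argument("levels must be >= 2")
  h0 <- scn$mesh$target_h_patch
  out <- lapply(seq_len(levels), function(l) {
    sc <- scn
    sc$mesh <- mesh_spec(h0 * 2^(-(l - 1) / 2),
                         max(scn$mesh$target_h_bulk * 2^(-(l - 1) / 2),
                             scn$mesh$target_h_patch),
                         refinement_levels = 1)
    sol <- solve_steady(sc)
    amp <- junction_amplitude(sol)
    peak <- if (length(sc$open_orai))
      peak_at_patch(sol, kind = "ORAI", index = sc$open_orai[1])
      else NA_real_
    data.frame(level = l, h_patch = sc$mesh$target_h_patch,
               amplitude_nM = amp, orai_peak_uM = peak)
  })
  do.call(rbind, out)
}
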