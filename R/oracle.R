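# Closed-form and Monte-Carlo reference solutions: steady-state half-space
# Green's functions for membrane point and disc sources, superposition, and
# Brownian first-exit residence times.  These are exact in their idealised
# geometries (a source on an infinite reflecting plane bounding a half-space
# of uniform diffusivity) and serve to verify the finite-volume solver and to
# calibrate pore-patch radii.

#' Steady concentration near a membrane point source
#'
#' A source of molar rate `Q` on an infinite reflecting plane, releasing into
#' a half-space with diffusivity `D`, raises the steady concentration at
#' distance `r` by `Q / (2 pi D r)` above background.
#'
#' @param Q molar rate (mol/s).
#' @param D diffusivity (um^2/s).
#' @param r distance from the source (nm); vectorised.
#' @param C_bg background concentration (nM).
#' @return concentration (nM).
#' @examples
#' point_source_conc(2.285e-21, 220, 20, 30)  # ~112.6 nM
#' @export
point_source_conc <- function(Q, D, r, C_bg = 0) {
  if (D <= 0) invalid_argument("D must be > 0")
  if (any(r <= 0)) abort_socesim("socesim_singularity_error",
                                 "r must be > 0 (point-source singularity)")
  C_bg + molm3_to_nM(Q / (2 * pi * (D * UM2_S) * (r * NM)))
}

#' Steady concentration at the centre of a uniform-flux membrane disc
#'
#' A disc of radius `a` on a reflecting plane carrying total molar rate `Q`
#' uniformly raises the steady concentration at its centre by
#' `Q / (pi a D)`; the disc-surface average is `8/(3 pi)` times the centre
#' value.  Used to calibrate pore radii against printed mouth-concentration
#' anchors.
#'
#' @param Q total molar rate (mol/s).
#' @param a disc radius (nm).
#' @param D diffusivity (um^2/s).
#' @param C_bg background concentration (nM).
#' @param average if `TRUE` return the disc-surface average instead of the
#'   centre value.
#' @return concentration (nM).
#' @examples
#' disc_center_conc(2.285e-21, 0.8, 220)  # ~4133 nM = 4.1 uM
#' @export
disc_center_conc <- function(Q, a, D, C_bg = 0, average = FALSE) {
  if (a <= 0) abort_socesim("socesim_singularity_error",
                            "disc radius must be > 0")
  if (D <= 0) invalid_argument("D must be > 0")
  inc <- Q / (pi * (a * NM) * (D * UM2_S))
  if (average) inc <- inc * 8 / (3 * pi)
  C_bg + molm3_to_nM(inc)
}

#' Superpose membrane sources at evaluation points
#'
#' Sum of half-space point-source contributions plus background; valid for
#' the linear, pump-free steady problem.
#'
#' @param sources list of source specs, each a list with `position`
#'   (length-3, nm) and `molar_rate` (mol/s); an optional `disc_radius` is
#'   accepted for bookkeeping but sources are evaluated as points.
#' @param D diffusivity (um^2/s).
#' @param eval_points n x 3 matrix of points (nm), distinct from source
#'   positions.
#' @param C_bg background concentration (nM).
#' @return concentrations (nM) at the evaluation points.
#' @export
superpose <- function(sources, D, eval_points, C_bg = 0) {
  eval_points <- rbind(eval_points)
  out <- rep(C_bg, nrow(eval_points))
  for (s in sources) {
    dr <- sweep(eval_points, 2, s$position)
    r <- sqrt(rowSums(dr^2))
    if (any(r < 1e-9)) abort_socesim("socesim_singularity_error",
                                     "evaluation point coincides with a source")
    out <- out + point_source_conc(s$molar_rate, D, r)
  }
  out
}

#' Monte-Carlo residence time in a junction-like cylinder
#'
#' First-exit time of Brownian walkers started at the cylinder axis, with
#' reflecting top and bottom faces (PM and ER) and an absorbing lateral rim.
#' Because the axial faces reflect, the first-exit time is governed by the
#' lateral diffusion alone; for a walker started at the centre of a disc of
#' radius R the exact mean exit time is `R^2 / (4 D)`.
#'
#' @param region list with `radius` (nm) and optionally `height` (nm,
#'   bookkeeping only).
#' @param D diffusivity (um^2/s).
#' @param n_walkers number of walkers (>= 100).
#' @param seed integer RNG seed; the same seed reproduces the same result.
#' @param dt time step (s); default `R^2/(4 D) / 400`.
#' @return list with `mean` and `se` of the exit time (s), `n_walkers`,
#'   `seed` and `dt`.
#' @export
mc_residence_time <- function(region, D, n_walkers = 1000, seed = 1,
                              dt = NULL) {
  if (D <= 0) invalid_argument("D must be > 0")
  if (n_walkers < 100) invalid_argument("n_walkers must be >= 100")
  R <- region$radius * NM
  Dm <- D * UM2_S
  tau <- R^2 / (4 * Dm)
  if (is.null(dt)) dt <- tau / 400
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  x <- numeric(n_walkers); y <- numeric(n_walkers)
  exit <- rep(NA_real_, n_walkers)
  alive <- seq_len(n_walkers)
  sd_step <- sqrt(2 * Dm * dt)
  t <- 0
  max_steps <- 400L * 50L
  for (step in seq_len(max_steps)) {
    t <- t + dt
    n <- length(alive)
    x[alive] <- x[alive] + stats::rnorm(n, sd = sd_step)
    y[alive] <- y[alive] + stats::rnorm(n, sd = sd_step)
    out <- x[alive]^2 + y[alive]^2 >= R^2
    if (any(out)) {
      exit[alive[out]] <- t
      alive <- alive[!out]
    }
    if (length(alive) == 0) break
  }
  exit[is.na(exit)] <- t  # censored tail (negligible for max_steps >> tau/dt)
  list(mean = mean(exit), se = stats::sd(exit) / sqrt(n_walkers),
       n_walkers = n_walkers, seed = seed, dt = dt)
}

#' Calibrate the IP3R pore-patch radius against printed anchors
#'
#' The IP3R flux law couples the pore rate to the area-averaged mouth
#' concentrations on both faces, which themselves depend on the rate through
#' the disc self-terms `8/(3 pi^2) * Q/(a D)` and, on the luminal side, the
#' quasi-1D access resistance of the cone to the fixed-concentration ER bulk.
#' This gives a closed-form self-consistent rate
#' `Q(a) = alpha (C_S0 - C_C0) / (1 + alpha (kS + kC + R_env))`, from which
#' the cytosolic mouth-centre concentration and the sensed ER average over
#' the cubic sensing region follow.  The returned radius minimises the summed
#' squared relative error to the two anchors.
#'
#' @param params a [flux_params()].
#' @param geom a [junction_geometry()].
#' @param ip3r_depth depth of the IP3R ring below the PM (nm).
#' @param sensing_edge sensing cube edge (nm).
#' @param anchor_cc_center target cytosolic mouth-centre concentration (uM).
#' @param anchor_sensed target sensed ER average (uM).
#' @param radii candidate radii (nm).
#' @param sensed_margin minimum distance (uM) the sensed average must keep
#'   below the half-open gating threshold at 360 uM.  The anchor itself sits
#'   30 uM below that threshold; a calibration leaving the sensed value at
#'   the band edge would misclassify the gating state, which is the
#'   qualitative behaviour the open-fraction function encodes.
#' @return the calibrated radius (nm), with attribute `detail` (a data frame
#'   of the model predictions over `radii`).
#' @export
calibrate_ip3r_radius <- function(params = flux_params(),
                                  geom = junction_geometry(),
                                  ip3r_depth = 90, sensing_edge = 108,
                                  anchor_cc_center = 16, anchor_sensed = 330,
                                  radii = seq(2, 30, by = 0.5),
                                  sensed_margin = 15) {
  alpha <- params$I_IP3R / (params$z * params$F) / (params$cs0 - params$cc0)
  # quasi-1D cone resistance from one mixing length below the ring to the
  # ER-bulk Dirichlet face: integral of dz / (pi r(z)^2 D_S)
  slope <- (geom$cone_bottom_radius - geom$cone_top_radius) / geom$cone_depth
  mix <- 50  # nm, near-field already counted in the disc self-term
  z1 <- min(ip3r_depth + mix, geom$gap + geom$cone_depth)
  r1 <- cone_radius_at(geom, z1) * NM
  r2 <- geom$cone_bottom_radius * NM
  R_env <- (1 / slope) * (1 / r1 - 1 / r2) / (pi * params$ds)
  # average of 1/(2 pi r) over the sensing cube centred on the source (the
  # wall-clipped half cube has the same average by symmetry)
  n <- 41
  h <- sensing_edge * NM / n
  ax <- (seq_len(n) - (n + 1) / 2) * h
  g <- expand.grid(ax, ax, ax)
  rr <- sqrt(rowSums(g^2))
  c_cube <- mean(1 / (2 * pi * rr[rr > 0])) / params$ds
  kS <- (8 / (3 * pi^2)) / (radii * NM * params$ds)
  kC <- (8 / (3 * pi^2)) / (radii * NM * params$dc)
  Q <- alpha * (params$cs0 - params$cc0) / (1 + alpha * (kS + kC + R_env))
  cc_center <- molm3_to_uM(params$cc0 + Q / (pi * radii * NM * params$dc))
  sensed <- molm3_to_uM(params$cs0 - Q * (c_cube + R_env))
  err <- (cc_center / anchor_cc_center - 1)^2 + (sensed / anchor_sensed - 1)^2
  feasible <- sensed <= 360 - sensed_margin
  if (!any(feasible)) invalid_argument("no candidate radius keeps the sensed
    average below the gating threshold")
  err[!feasible] <- Inf
  best <- which.min(err)
  structure(radii[best],
            detail = data.frame(radius = radii, Q = Q,
                                cc_center_uM = cc_center,
                                sensed_uM = sensed, err = err))
}
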