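# Observables: scalar and field quantities derived from a steady solution --
# junction-average amplitude, pore-mouth peaks, sensed ER averages, spatial
# extent, ion bookkeeping (Little's-law residence time), SERCA operating
# points and planar cross-sections.

#' Junction-average calcium amplitude
#'
#' Volume average of the cytosolic calcium concentration over the junction
#' cylinder (radius `junction_radius`, height `gap`), minus the 30 nM resting
#' baseline.
#'
#' @param sol a [solve_steady()] solution.
#' @return amplitude (nM).
#' @export
junction_amplitude <- function(sol) {
  m <- sol$mesh
  analytic <- sum(sol$sq[m$sides_cyto] * m$junction$g) / sol$params$dc
  smooth <- sum(sol$w$cyto[m$junction$cells] * m$junction$w)
  molm3_to_nM(analytic + smooth)
}

#' Calcium concentration at a pore-patch centre
#'
#' The cytosolic (or luminal) field evaluated at the centre of the patch
#' disc: the analytic uniform-flux disc centre value of the patch's own rate
#' plus the environment (other kernels and the smooth remainder).  Pore-scale
#' peaks are the most discretisation-sensitive observable; the mesh level is
#' attached as an attribute.
#'
#' @param sol a [solve_steady()] solution.
#' @param kind patch kind (`"ORAI"`, `"IP3R"`, `"SERCA"`).
#' @param index patch index within its kind.
#' @param side `"cyto"` for the cytosolic mouth (default), `"er"` for the
#'   luminal mouth of IP3R/SERCA patches.
#' @return concentration (uM) with attribute `h_patch` (nm).
#' @export
peak_at_patch <- function(sol, kind, index, side = "cyto") {
  if (side == "er" && kind == "ORAI")
    invalid_argument("ORAI1 patches have no luminal face")
  v <- side_mouth(sol, side, kind, index, which = "center")
  if (is.na(v)) invalid_argument("no %s patch with index %d", kind, index)
  structure(molm3_to_uM(v), h_patch = sol$mesh$spec$target_h_patch)
}

#' Sensed ER average around an IP3R
#'
#' Volume average of the luminal calcium over the sensing cube of one IP3R
#' (the quantity the associated ORAI1 channel's open fraction responds to).
#'
#' @param sol a [solve_steady()] solution.
#' @param ip3r_index 1-based receptor index.
#' @return concentration (uM).
#' @export
sensing_average <- function(sol, ip3r_index) {
  if (length(sol$sensed) == 0)
    invalid_argument("layout has no IP3Rs (empty sensing region)")
  if (ip3r_index < 1 || ip3r_index > length(sol$sensed))
    invalid_argument("ip3r_index %d out of range", ip3r_index)
  molm3_to_uM(sol$sensed[ip3r_index])
}

#' Spatial extent of the microdomain at a threshold
#'
#' Area of the region on the horizontal plane `plane_depth` nanometres below
#' the PM where the cytosolic calcium increase above baseline reaches at
#' least `theta`.
#'
#' @param sol a [solve_steady()] solution.
#' @param theta classification threshold (nM), > 0.  The experimental
#'   threshold is not printed; no default is supplied.
#' @param plane_depth depth of the evaluation plane below the PM (nm);
#'   defaults to mid-junction.
#' @param n sampling resolution per axis.
#' @return area (um^2).
#' @export
spatial_extent <- function(sol, theta, plane_depth = NULL, n = 201) {
  if (missing(theta) || theta <= 0) invalid_argument("theta must be > 0 nM")
  g <- sol$mesh$geom
  if (is.null(plane_depth)) plane_depth <- g$gap / 2
  if (plane_depth < 0 || plane_depth > g$total_height)
    invalid_argument("plane lies outside the cytosolic domain")
  L <- g$box_side / 2
  ax <- seq(-L, L, length.out = n)
  pts <- as.matrix(expand.grid(x = ax, y = ax))
  pts <- cbind(pts, z = plane_depth)
  cc <- eval_conc(sol, pts, "cyto")
  dc <- molm3_to_nM(cc - sol$params$cc0)
  cell_area <- (ax[2] - ax[1])^2  # nm^2
  sum(dc >= theta, na.rm = TRUE) * cell_area * 1e-6  # nm^2 -> um^2
}

#' Ion bookkeeping for a steady scenario
#'
#' Ions entered through the open ORAI1 channels over the event window, the
#' average number of free calcium ions in the junction at steady state, and
#' the Little's-law mean residence time (free-ion content divided by the
#' channel influx in ions per second).
#'
#' @param sol a [solve_steady()] solution.
#' @return list with `ions_entered`, `free_ions_junction`,
#'   `residence_time_s` (`NA` when there is no influx).
#' @export
ion_bookkeeping <- function(sol) {
  scn <- sol$scenario
  dur <- diff(scn$event_window)
  NA_ <- socesim_constants$avogadro
  ions <- sum(sol$Q_orai) * dur * NA_
  conc <- sol$params$cc0 + nM_to_molm3(junction_amplitude(sol))
  free <- conc * sol$mesh$junction$volume * NA_
  influx <- (sum(sol$Q_orai) + sum(pmax(sol$Q_ip3r, 0))) * NA_
  list(ions_entered = ions,
       free_ions_junction = free,
       residence_time_s = if (influx > 0) free / influx else NA_real_)
}

#' SERCA operating point
#'
#' The cytosolic-mouth concentration and realised molar pumping rate of one
#' SERCA patch, for comparison with the closed-form pump curve at full ER.
#'
#' @param sol a [solve_steady()] solution.
#' @param pump_index 1-based pump index.
#' @return list with `cc_mouth_uM`, `cs_mouth_uM` and `rate` (mol/s,
#'   positive cytosol to ER).
#' @export
serca_operating_point <- function(sol, pump_index) {
  n <- length(patches_of(sol$scenario$layout, "SERCA"))
  if (pump_index < 1 || pump_index > n)
    invalid_argument("pump_index %d out of range (1..%d)", pump_index, n)
  list(cc_mouth_uM = molm3_to_uM(side_mouth(sol, "cyto", "SERCA", pump_index)),
       cs_mouth_uM = molm3_to_uM(side_mouth(sol, "er", "SERCA", pump_index)),
       rate = sol$R_serca[pump_index])
}

#' Planar cross-section of both concentration fields
#'
#' Samples the cytosolic and luminal fields on a vertical or horizontal
#' plane; each field is `NA` outside its sub-domain, so the two matrices
#' carry separate value ranges (dual colour scales).
#'
#' @param sol a [solve_steady()] solution.
#' @param axis plane normal: `"x"`, `"y"` (vertical planes) or `"z"`.
#' @param value coordinate of the plane along `axis` (nm).
#' @param n1,n2 sampling resolution of the two in-plane axes.
#' @return list with in-plane coordinate vectors `u`, `v` (nm) and matrices
#'   `cc`, `cs` (uM).
#' @export
cross_section <- function(sol, axis = "y", value = 0, n1 = 161, n2 = 161) {
  g <- sol$mesh$geom
  L <- g$box_side / 2
  axis <- match.arg(axis, c("x", "y", "z"))
  if (axis %in% c("x", "y")) {
    if (abs(value) > L) invalid_argument("plane outside the domain")
    u <- seq(-L, L, length.out = n1)
    v <- seq(0, g$total_height, length.out = n2)
    pts <- as.matrix(expand.grid(u = u, v = v))
    xyz <- if (axis == "y") cbind(pts[, 1], value, pts[, 2])
           else cbind(value, pts[, 1], pts[, 2])
  } else {
    if (value < 0 || value > g$total_height)
      invalid_argument("plane outside the domain")
    u <- seq(-L, L, length.out = n1)
    v <- seq(-L, L, length.out = n2)
    pts <- as.matrix(expand.grid(u = u, v = v))
    xyz <- cbind(pts[, 1], pts[, 2], value)
  }
  cc <- matrix(molm3_to_uM(eval_conc(sol, xyz, "cyto")), n1, n2)
  cs <- matrix(molm3_to_uM(eval_conc(sol, xyz, "er")), n1, n2)
  list(axis = axis, value = value, u = u, v = v, cc = cc, cs = cs)
}

#' Collect the standard observable set of a solved scenario
#'
#' @param sol a [solve_steady()] solution.
#' @param theta optional spatial-extent threshold (nM).
#' @param label scenario label for the output row.
#' @return one-row data frame.
#' @export
observable_set <- function(sol, theta = NULL, label = "scenario") {
  scn <- sol$scenario
  ions <- ion_bookkeeping(sol)
  rep <- sol$flux_report
  orai_peak <- if (length(scn$open_orai))
    max(vapply(scn$open_orai, function(i)
      as.numeric(peak_at_patch(sol, "ORAI", i)), 0)) else NA_real_
  ip3r_peak <- if (length(scn$open_ip3r))
    max(vapply(scn$open_ip3r, function(i)
      as.numeric(peak_at_patch(sol, "IP3R", i)), 0)) else NA_real_
  sensed_open <- if (length(scn$open_ip3r) && length(sol$sensed))
    min(sol$sensed[scn$open_ip3r]) else NA_real_
  serca_lum <- rep$cs_mouth_uM[rep$kind == "SERCA"]
  data.frame(
    scenario = label,
    n_orai_open = length(scn$open_orai),
    n_ip3r_open = length(scn$open_ip3r),
    D_S_um2_s = scn$params$D_S,
    junction_amplitude_nM = junction_amplitude(sol),
    orai_peak_uM = orai_peak,
    ip3r_peak_uM = ip3r_peak,
    sensed_open_uM = if (is.na(sensed_open)) NA_real_
                     else molm3_to_uM(sensed_open),
    max_serca_luminal_uM = if (length(serca_lum)) max(serca_lum) else NA_real_,
    ions_entered = ions$ions_entered,
    free_ions_junction = ions$free_ions_junction,
    residence_time_ms = ions$residence_time_s * 1e3,
    spatial_extent_um2 = if (is.null(theta)) NA_real_
                         else spatial_extent(sol, theta),
    max_orai_f = if (length(scn$open_orai)) max(sol$f) else NA_real_,
    conservation_rel_err = sol$conservation$rel_err,
    stringsAsFactors = FALSE)
}
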