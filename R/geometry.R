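# Geometry of the ER-PM junction: a box-shaped cytosolic domain containing a
# truncated-cone sub-PM ER, a 15 nm junctional gap between the plasma membrane
# (PM, z = 0) and the flat top face of the ER, and circular flux patches
# (ORAI1 channels on the PM, SERCA pumps on the ER top face, IP3 receptors on
# the cone lateral face).
#
# Coordinates: origin at the centre of the PM, z increasing downward into the
# cell.  All lengths in nanometres.

#' Junction geometry
#'
#' Dimensions of the computational domain: a `box_side` x `box_side` x
#' `total_height` cytosolic box whose top face is the plasma membrane,
#' containing a truncated-cone sub-PM ER whose flat top face lies `gap`
#' nanometres below the PM and whose bottom face coincides with the bottom of
#' the box (`total_height = gap + cone_depth`).  The ER-PM junction proper is
#' the cylinder of radius `junction_radius` between the PM and the ER top
#' face.
#'
#' @param box_side lateral extent of the cytosolic box (nm).
#' @param gap PM-to-ER distance (nm).
#' @param junction_radius radius of the junction cylinder (nm).
#' @param cone_top_radius radius of the ER top face (nm).
#' @param cone_bottom_radius radius of the ER bottom face (nm).
#' @param cone_depth depth of the sub-PM ER cone (nm).
#' @return An object of class `junction_geometry`.
#' @examples
#' g <- junction_geometry()
#' junction_volume(g)  # pi * 100^2 * 15 nm^3
#' @export
junction_geometry <- function(box_side = 400, gap = 15, junction_radius = 100,
                              cone_top_radius = 100, cone_bottom_radius = 200,
                              cone_depth = 485) {
  if (gap <= 0) geometry_violation("gap must be > 0 (got %g nm)", gap)
  if (cone_top_radius > cone_bottom_radius)
    geometry_violation("cone_top_radius (%g) must not exceed cone_bottom_radius (%g)",
                       cone_top_radius, cone_bottom_radius)
  if (2 * cone_bottom_radius > box_side)
    geometry_violation("cone bottom (diameter %g) does not fit in box of side %g",
                       2 * cone_bottom_radius, box_side)
  if (cone_depth < 0) geometry_violation("cone_depth must be >= 0")
  if (junction_radius < 0) invalid_argument("junction_radius must be >= 0")
  structure(list(
    box_side = box_side, gap = gap, junction_radius = junction_radius,
    cone_top_radius = cone_top_radius, cone_bottom_radius = cone_bottom_radius,
    cone_depth = cone_depth, total_height = gap + cone_depth,
    has_er = cone_bottom_radius > 0 && cone_depth > 0
  ), class = "junction_geometry")
}

#' @export
print.junction_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "ER-PM junction geometry (nm):\n",
    "  box %g x %g x %g, gap %g, junction radius %g\n",
    "  sub-PM ER cone: top r = %g, bottom r = %g, depth %g\n"),
    x$box_side, x$box_side, x$total_height, x$gap, x$junction_radius,
    x$cone_top_radius, x$cone_bottom_radius, x$cone_depth))
  invisible(x)
}

#' Volume of the junction cylinder (nm^3)
#'
#' @param geom a [junction_geometry()].
#' @return volume in nm^3 (`pi * junction_radius^2 * gap`).
#' @export
junction_volume <- function(geom) {
  pi * geom$junction_radius^2 * geom$gap
}

#' Volume of the sub-PM ER cone frustum (nm^3)
#'
#' @param geom a [junction_geometry()].
#' @return volume in nm^3, `(pi * depth / 3) * (R^2 + R r + r^2)`.
#' @export
cone_volume <- function(geom) {
  R <- geom$cone_bottom_radius; r <- geom$cone_top_radius
  pi * geom$cone_depth / 3 * (R^2 + R * r + r^2)
}

#' Cone (ER) radius at depth z below the PM
#'
#' Linear taper from `cone_top_radius` at `z = gap` to `cone_bottom_radius`
#' at `z = gap + cone_depth`.  Outside that range the ER does not exist and
#' `NA` is returned.
#'
#' @param geom a [junction_geometry()].
#' @param z depth below the PM (nm); vectorised.
#' @return radius (nm) or NA outside the cone.
#' @export
cone_radius_at <- function(geom, z) {
  r <- geom$cone_top_radius +
    (geom$cone_bottom_radius - geom$cone_top_radius) *
      (z - geom$gap) / geom$cone_depth
  r[z < geom$gap | z > geom$gap + geom$cone_depth] <- NA_real_
  r
}

is_in_er <- function(geom, x, y, z) {
  if (!geom$has_er) return(rep(FALSE, length(x)))
  r <- cone_radius_at(geom, z)
  !is.na(r) & (x^2 + y^2 < r^2) & z > geom$gap
}

#' Equally spaced positions on a ring
#'
#' `n` points on the circle of radius `radius` centred on the vertical axis
#' at depth `z`, the first at angle 0, counter-clockwise.  The distance
#' between adjacent points is `2 * radius * sin(pi / n)`.
#'
#' @param n number of points (>= 1).
#' @param radius ring radius (nm).
#' @param z depth below the PM (nm).
#' @return an `n` x 3 matrix of coordinates (nm) with attribute `spacing`
#'   (nm; `NA` for `n = 1`).
#' @examples
#' p <- ring_positions(5, 40)
#' attr(p, "spacing")  # 47.0 nm
#' @export
ring_positions <- function(n, radius, z = 0) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n))
    invalid_argument("n must be a positive integer (got %s)", format(n))
  if (radius < 0) invalid_argument("radius must be >= 0")
  theta <- 2 * pi * (seq_len(n) - 1) / n
  pts <- cbind(x = radius * cos(theta), y = radius * sin(theta), z = rep(z, n))
  attr(pts, "spacing") <- if (n >= 2) 2 * radius * sin(pi / n) else NA_real_
  pts
}

#' Circular flux patch on a membrane
#'
#' @param kind one of `"ORAI"`, `"IP3R"`, `"SERCA"`.
#' @param center length-3 numeric, patch centre (nm).
#' @param radius patch disc radius (nm); its area `pi * radius^2` is the pore
#'   surface of the flux laws.
#' @param surface host surface: `"PM"`, `"ER_top_face"` or `"ER_lateral_face"`.
#' @param index integer patch index within its kind (1-based).
#' @return an object of class `pore_patch`.
#' @export
pore_patch <- function(kind, center, radius, surface, index) {
  kind <- match.arg(kind, c("ORAI", "IP3R", "SERCA"))
  surface <- match.arg(surface, c("PM", "ER_top_face", "ER_lateral_face"))
  if (radius <= 0) invalid_argument("patch radius must be > 0")
  if (length(center) != 3) invalid_argument("center must have 3 coordinates")
  structure(list(kind = kind, center = as.numeric(center), radius = radius,
                 surface = surface, index = as.integer(index),
                 area = pi * radius^2),
            class = "pore_patch")
}

#' IP3R patches on the cone lateral face
#'
#' Places `n` IP3R pore patches on the ring where the cone lateral surface
#' crosses the horizontal plane `depth_below_pm` nanometres below the PM; the
#' ring radius follows the cone's linear taper.  Patch normals point out of
#' the ER, into the cytosol.
#'
#' @param geom a [junction_geometry()].
#' @param n number of receptors.
#' @param depth_below_pm depth of the ring below the PM (nm); must satisfy
#'   `gap < depth_below_pm < gap + cone_depth`.
#' @param radius pore-patch radius (nm).
#' @return list of [pore_patch()] objects, with attribute `ring_radius` (nm)
#'   and `spacing` (nm).
#' @export
ip3r_positions <- function(geom, n, depth_below_pm, radius = 7) {
  if (!(depth_below_pm > geom$gap &&
        depth_below_pm < geom$gap + geom$cone_depth))
    geometry_violation(
      "IP3R depth %g nm lies outside the cone (gap %g .. %g nm)",
      depth_below_pm, geom$gap, geom$gap + geom$cone_depth)
  ring_r <- cone_radius_at(geom, depth_below_pm)
  pts <- ring_positions(n, ring_r, z = depth_below_pm)
  patches <- lapply(seq_len(n), function(i) {
    pore_patch("IP3R", pts[i, ], radius, "ER_lateral_face", i)
  })
  attr(patches, "ring_radius") <- ring_r
  attr(patches, "spacing") <- attr(pts, "spacing")
  patches
}

#' Channel and pump layout of the junction
#'
#' The default layout is the canonical arrangement: 5 ORAI1 channels on a
#' 40 nm ring on the PM (47 nm spacing), 10 SERCA pumps on a 70 nm ring on
#' the ER top face (~44 nm spacing), and 8 IP3 receptors on the cone lateral
#' face 90 nm below the PM (~88 nm spacing).  Each ORAI1 is associated with
#' its nearest IP3R (ties broken by the lowest IP3R index): the ER calcium
#' concentration sensed in the cube of edge `sensing_edge` around that IP3R's
#' luminal mouth sets the ORAI1 open fraction.
#'
#' @param geom a [junction_geometry()].
#' @param n_orai,orai_ring_radius,orai_radius number, ring radius and pore
#'   radius (nm) of the ORAI1 channels.
#' @param n_serca,serca_ring_radius,serca_radius idem for SERCA pumps.
#' @param n_ip3r,ip3r_depth,ip3r_radius number, depth below the PM (nm) and
#'   pore-patch radius (nm) of the IP3 receptors (`n_ip3r = 0` omits them).
#' @param sensing_edge edge of the cubic ER sensing region (nm).
#' @return An object of class `channel_layout`: a list of [pore_patch()]es
#'   with attributes `orai_to_ip3r` (integer map) and `sensing_edge`.
#' @export
channel_layout <- function(geom,
                           n_orai = 5, orai_ring_radius = 40, orai_radius = 0.8,
                           n_serca = 10, serca_ring_radius = 70, serca_radius = 5,
                           n_ip3r = 8, ip3r_depth = 90, ip3r_radius = 7,
                           sensing_edge = 108) {
  if (sensing_edge <= 0) invalid_argument("sensing_edge must be > 0")
  patches <- list()
  if (n_orai > 0) {
    if (orai_ring_radius + orai_radius > geom$box_side / 2)
      geometry_violation("ORAI ring leaves the PM")
    pts <- ring_positions(n_orai, orai_ring_radius, z = 0)
    patches <- c(patches, lapply(seq_len(n_orai), function(i)
      pore_patch("ORAI", pts[i, ], orai_radius, "PM", i)))
  }
  if (n_serca > 0) {
    if (serca_ring_radius + serca_radius > geom$cone_top_radius)
      geometry_violation("SERCA ring leaves the ER top face")
    pts <- ring_positions(n_serca, serca_ring_radius, z = geom$gap)
    patches <- c(patches, lapply(seq_len(n_serca), function(i)
      pore_patch("SERCA", pts[i, ], serca_radius, "ER_top_face", i)))
  }
  if (n_ip3r > 0) {
    patches <- c(patches, ip3r_positions(geom, n_ip3r, ip3r_depth, ip3r_radius))
  }
  check_patch_overlap(patches)
  layout <- structure(patches, class = "channel_layout")
  attr(layout, "sensing_edge") <- sensing_edge
  attr(layout, "orai_to_ip3r") <- map_orai_to_ip3r(layout)
  attr(layout, "args") <- list(
    n_orai = n_orai, orai_ring_radius = orai_ring_radius,
    orai_radius = orai_radius, n_serca = n_serca,
    serca_ring_radius = serca_ring_radius, serca_radius = serca_radius,
    n_ip3r = n_ip3r, ip3r_depth = ip3r_depth, ip3r_radius = ip3r_radius,
    sensing_edge = sensing_edge)
  layout
}

check_patch_overlap <- function(patches) {
  n <- length(patches)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- patches[[i]]; b <- patches[[j]]
    if (a$surface != b$surface) next
    d <- sqrt(sum((a$center - b$center)^2))
    if (d < a$radius + b$radius)
      geometry_violation("patches %s#%d and %s#%d overlap on %s (d = %.2f nm)",
                         a$kind, a$index, b$kind, b$index, a$surface, d)
  }
  invisible(TRUE)
}

patch_table <- function(layout) {
  do.call(rbind, lapply(layout, function(p)
    data.frame(kind = p$kind, index = p$index,
               x = p$center[1], y = p$center[2], z = p$center[3],
               radius = p$radius, surface = p$surface,
               stringsAsFactors = FALSE)))
}

patches_of <- function(layout, kind) {
  Filter(function(p) p$kind == kind, unclass(layout))
}

map_orai_to_ip3r <- function(layout) {
  orai <- patches_of(layout, "ORAI")
  ip3r <- patches_of(layout, "IP3R")
  if (length(orai) == 0) return(integer(0))
  if (length(ip3r) == 0) return(rep(NA_integer_, length(orai)))
  vapply(orai, function(o) {
    d <- vapply(ip3r, function(q) sqrt(sum((o$center - q$center)^2)), 0)
    which.min(d)  # which.min takes the first (lowest index) on ties
  }, 0L)
}

#' ER sensing region of an IP3 receptor
#'
#' The axis-aligned cube of edge `sensing_edge` centred on the IP3R's luminal
#' pore centre, intersected with the ER domain.  The average luminal calcium
#' concentration over this region is the locally sensed ER calcium that sets
#' the associated ORAI1 channel's open fraction.
#'
#' @param layout a [channel_layout()].
#' @param ip3r_index 1-based IP3R index.
#' @param geom a [junction_geometry()].
#' @return An object of class `sensing_region` with the cube centre, edge and
#'   bounds (nm).
#' @export
sensing_region <- function(layout, ip3r_index, geom) {
  edge <- attr(layout, "sensing_edge")
  if (is.null(edge) || edge <= 0)
    invalid_argument("layout has a degenerate sensing_edge")
  ip3r <- patches_of(layout, "IP3R")
  if (ip3r_index < 1 || ip3r_index > length(ip3r))
    invalid_argument("ip3r_index %d out of range (1..%d)",
                     ip3r_index, length(ip3r))
  ctr <- ip3r[[ip3r_index]]$center
  structure(list(center = ctr, edge = edge,
                 lower = ctr - edge / 2, upper = ctr + edge / 2),
            class = "sensing_region")
}

#' Volume of a sensing region clipped to the ER (nm^3)
#'
#' Midpoint quadrature of the cube-cone intersection.
#'
#' @param region a [sensing_region()].
#' @param geom a [junction_geometry()].
#' @param n quadrature points per axis.
#' @return volume in nm^3.
#' @export
sensing_volume <- function(region, geom, n = 40) {
  g <- sensing_quadrature(region, geom, n)
  sum(g$inside) * g$dv
}

# midpoint grid over the cube; `inside` flags points in the ER
sensing_quadrature <- function(region, geom, n = 14) {
  h <- region$edge / n
  ax <- region$lower[1] + (seq_len(n) - 0.5) * h
  ay <- region$lower[2] + (seq_len(n) - 0.5) * h
  az <- region$lower[3] + (seq_len(n) - 0.5) * h
  pts <- expand.grid(x = ax, y = ay, z = az, KEEP.OUT.ATTRS = FALSE)
  inside <- is_in_er(geom, pts$x, pts$y, pts$z)
  list(points = as.matrix(pts), inside = inside, dv = h^3)
}

#' Write a plain-text layout manifest
#'
#' One row per patch: kind, index, centre coordinates, radius and host
#' surface, plus the ORAI to IP3R sensing associations.
#'
#' @param layout a [channel_layout()].
#' @param path output file (TSV).
#' @return the manifest data frame, invisibly.
#' @export
write_layout_manifest <- function(layout, path) {
  tab <- patch_table(layout)
  map <- attr(layout, "orai_to_ip3r")
  tab$senses_ip3r <- NA_integer_
  tab$senses_ip3r[tab$kind == "ORAI"] <- map[tab$index[tab$kind == "ORAI"]]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
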