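# Minimal legacy-VTK (ASCII, RECTILINEAR_GRID) writer for the cell-centered
# concentration fields.  The grid is rectilinear, so this standard format
# describes it exactly; files open in ParaView/VisIt.

#' Write the concentration fields to a legacy VTK file
#'
#' Cell data: cytosolic and luminal calcium (uM; -1 outside the respective
#' sub-domain) and the sub-domain id.
#'
#' @param sol a [solve_steady()] solution.
#' @param path output file (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_vtk_fields <- function(sol, path) {
  m <- sol$mesh
  cc <- rep(-1, m$ncell); cs <- rep(-1, m$ncell)
  ctr <- as.matrix(expand.grid(x = m$xc, y = m$yc, z = m$zc))
  cyt <- m$dom == 1L
  cc[cyt] <- molm3_to_uM(eval_conc(sol, ctr[cyt, , drop = FALSE], "cyto"))
  cs[!cyt] <- molm3_to_uM(eval_conc(sol, ctr[!cyt, , drop = FALSE], "er"))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(formatC(x, format = "g", digits = 9),
                           collapse = " ")
  wl("# vtk DataFile Version 3.0")
  wl("socesim concentration fields (nm grid, uM cell data)")
  wl("ASCII")
  wl("DATASET RECTILINEAR_GRID")
  wl("DIMENSIONS %d %d %d", m$nx + 1L, m$ny + 1L, m$nz + 1L)
  wl("X_COORDINATES %d double", m$nx + 1L); wl("%s", num(m$xs))
  wl("Y_COORDINATES %d double", m$ny + 1L); wl("%s", num(m$ys))
  wl("Z_COORDINATES %d double", m$nz + 1L); wl("%s", num(m$zs))
  wl("CELL_DATA %d", m$ncell)
  for (fld in list(list("calcium_cytosol_uM", cc),
                   list("calcium_er_uM", cs),
                   list("domain", as.numeric(m$dom)))) {
    wl("SCALARS %s double 1", fld[[1]])
    wl("LOOKUP_TABLE default")
    writeLines(vapply(split(fld[[2]],
                            ceiling(seq_along(fld[[2]]) / 9)), num, ""), con)
  }
  invisible(path)
}

#' Export a cross-section as a two-panel PNG
#'
#' @param cs a [cross_section()] result.
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
export_cross_section_png <- function(cs, path, width = 1200, height = 600) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  for (fld in c("cc", "cs")) {
    z <- cs[[fld]]
    ttl <- if (fld == "cc") "cytosolic Ca (uM)" else "ER Ca (uM)"
    graphics::image(cs$u, cs$v, z, col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "u (nm)", ylab = "v (nm)", main = ttl,
                    ylim = if (cs$axis %in% c("x", "y")) rev(range(cs$v))
                           else range(cs$v))
  }
  invisible(path)
}
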