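# Discretisation: a graded tensor-product (rectilinear) grid over the box,
# split into the cytosolic and ER (cone) sub-domains, with cell-centered
# finite-volume Laplace operators per sub-domain and boundary-face tables.
#
# Pore fluxes are not resolved geometrically.  Each open patch contributes an
# analytic half-space Green's-function field u = Q / (2 pi D r) centred on a
# point of the discrete boundary; the grid solves only the smooth remainder
# w, with Neumann data that cancels the analytic field's flux across every
# boundary face (the "compensation" vectors below) and Dirichlet data that
# pins the total field on the open boundaries.  Because u and the Dirichlet
# compensation both scale as Q/D, the assembled operator is geometry-only and
# one Cholesky factorisation per sub-domain serves every scenario, diffusion
# coefficient and gating state.

#' Mesh specification
#'
#' @param target_h_patch grid spacing (nm) in the refined zone containing the
#'   junction and all patches.  Patches with radius >= 2 nm must satisfy
#'   `target_h_patch <= 2 * radius` so that their footprint spans at least a
#'   cell; sub-grid pores (the 0.8 nm ORAI1 pore) are represented by the
#'   analytic near field and only their position must be resolved.
#' @param target_h_bulk grid spacing (nm) far from the junction.
#' @param refinement_levels number of refinement levels used by
#'   [convergence_study()].
#' @return An object of class `mesh_spec`.
#' @export
mesh_spec <- function(target_h_patch = 6, target_h_bulk = 25,
                      refinement_levels = 1) {
  if (target_h_patch <= 0 || target_h_bulk <= 0)
    invalid_argument("mesh spacings must be > 0")
  if (target_h_patch > target_h_bulk)
    invalid_argument("target_h_patch must not exceed target_h_bulk")
  structure(list(target_h_patch = target_h_patch,
                 target_h_bulk = target_h_bulk,
                 refinement_levels = refinement_levels),
            class = "mesh_spec")
}

# widths of a graded 1D segment of length L, spacing h0 at one end and h1 at
# the other, geometric progression, scaled to fit exactly
graded_widths <- function(L, h0, h1) {
  if (L <= 0) return(numeric(0))
  n <- max(1L, ceiling(2 * L / (h0 + h1)))
  if (n == 1) return(L)
  q <- (h1 / h0)^(1 / (n - 1))
  w <- h0 * q^(0:(n - 1))
  w * L / sum(w)
}

axis_lines <- function(breaks, hs) {
  stopifnot(length(hs) == length(breaks))
  out <- breaks[1]
  for (s in seq_len(length(breaks) - 1)) {
    w <- graded_widths(breaks[s + 1] - breaks[s], hs[s], hs[s + 1])
    out <- c(out, breaks[s] + cumsum(w))
  }
  # guard against floating drift on the break positions
  out[length(out)] <- breaks[length(breaks)]
  out
}

mesh_cache_env <- new.env(parent = emptyenv())

# Bounded LRU store: meshes and factorisations are large, so the cache keeps
# only the most recently used entries within a byte budget per type
# (options socesim.mesh_cache_bytes / socesim.factor_cache_bytes).
cache_budget <- function(type) {
  getOption(paste0("socesim.", type, "_cache_bytes"),
            if (type == "factor") 1.2e9 else 5e8)
}

# evict least-recently-used entries of `type` until their total size is at
# most `target` bytes; `protect` is never evicted
cache_trim <- function(type, target, protect = NULL) {
  entries <- ls(mesh_cache_env)
  same <- entries[vapply(entries, function(k)
    mesh_cache_env[[k]]$type == type, TRUE)]
  evicted <- FALSE
  repeat {
    tot <- sum(vapply(same, function(k) mesh_cache_env[[k]]$bytes, 0))
    cand <- setdiff(same, protect)
    if (tot <= target || !length(cand)) break
    stamps <- vapply(cand, function(k)
      as.numeric(mesh_cache_env[[k]]$stamp), 0)
    drop <- cand[which.min(stamps)]
    rm(list = drop, envir = mesh_cache_env)
    same <- setdiff(same, drop)
    evicted <- TRUE
  }
  if (evicted) gc(verbose = FALSE)
  invisible(NULL)
}

cache_put <- function(key, value, type) {
  mesh_cache_env[[key]] <- list(value = value, type = type,
                                bytes = as.numeric(object.size(value)),
                                stamp = Sys.time())
  cache_trim(type, cache_budget(type), protect = key)
  invisible(value)
}

cache_get <- function(key) {
  e <- mesh_cache_env[[key]]
  if (is.null(e)) return(NULL)
  e$stamp <- Sys.time()
  mesh_cache_env[[key]] <- e
  e$value
}

mesh_cache_key <- function(geom, layout, spec) {
  tab <- patch_table(layout)
  paste(collapse = "|", c(
    sprintf("%.6g", unlist(geom[c("box_side", "gap", "junction_radius",
                                  "cone_top_radius", "cone_bottom_radius",
                                  "cone_depth")])),
    sprintf("%.6g", c(spec$target_h_patch, spec$target_h_bulk)),
    sprintf("%.6g", attr(layout, "sensing_edge")),
    apply(tab, 1, paste, collapse = ",")))
}

#' Clear the mesh/factorisation cache
#'
#' Factorised operators are cached per (geometry, layout, mesh) so that all
#' scenarios sharing a discretisation reuse them.  This drops the cache.
#' @return invisibly, the number of entries dropped.
#' @export
clear_mesh_cache <- function() {
  n <- length(ls(mesh_cache_env))
  rm(list = ls(mesh_cache_env), envir = mesh_cache_env)
  invisible(n)
}

#' Build the discretised junction domain
#'
#' Constructs the graded rectilinear grid, classifies cells into the cytosol
#' (box minus cone) and ER (cone) sub-domains sharing the ER-membrane
#' interface, assembles the finite-volume operators, locates every pore patch
#' on the discrete boundary and precomputes the analytic compensation data
#' used by the solver.  Results are cached (see [clear_mesh_cache()]).
#'
#' @param geom a [junction_geometry()].
#' @param layout a [channel_layout()].
#' @param mesh a [mesh_spec()].
#' @return An object of class `junction_mesh`.
#' @export
build_geometry <- function(geom, layout, mesh = mesh_spec()) {
  key <- mesh_cache_key(geom, layout, mesh)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)

  # finite patches must span at least half a cell
  for (p in layout) {
    if (p$radius >= 2 && mesh$target_h_patch > 2 * p$radius)
      mesh_resolution_error(
        "patch %s#%d (radius %.3g nm) unresolved at target_h_patch = %g nm",
        p$kind, p$index, p$radius, mesh$target_h_patch)
  }

  hf <- mesh$target_h_patch
  hb <- mesh$target_h_bulk
  L <- geom$box_side / 2
  tab <- patch_table(layout)
  fine_r <- min(L, max(geom$junction_radius,
                       max(abs(c(tab$x, tab$y))) + max(tab$radius)) + 15)
  lat_breaks <- if (fine_r >= L) c(-L, L) else c(-L, -fine_r, fine_r, L)
  lat_hs <- if (fine_r >= L) c(hf, hf) else c(hb, hf, hf, hb)
  xs <- axis_lines(lat_breaks, lat_hs)
  ys <- xs
  H <- geom$total_height
  hz_gap <- min(hf, geom$gap / 4)
  fine_z <- min(H, max(geom$gap, max(tab$z) + 40))
  if (fine_z < H) {
    zs <- axis_lines(c(0, geom$gap, fine_z, H),
                     c(hz_gap, hz_gap, 1.5 * hf, hb))
  } else {
    zs <- axis_lines(c(0, geom$gap, H), c(hz_gap, hz_gap, hf))
  }

  nx <- length(xs) - 1L; ny <- length(ys) - 1L; nz <- length(zs) - 1L
  xc <- (xs[-1] + xs[-length(xs)]) / 2
  yc <- (ys[-1] + ys[-length(ys)]) / 2
  zc <- (zs[-1] + zs[-length(zs)]) / 2
  dx <- diff(xs); dy <- diff(ys); dz <- diff(zs)

  # cell classification (1 = cytosol, 2 = ER)
  dom <- array(1L, dim = c(nx, ny, nz))
  if (geom$has_er) {
    rz <- cone_radius_at(geom, zc)
    for (k in seq_len(nz)) {
      if (is.na(rz[k]) || zc[k] <= geom$gap) next
      er2 <- outer(xc^2, yc^2, "+") < rz[k]^2
      dom[, , k][er2] <- 2L
    }
  }
  ncell <- nx * ny * nz
  domv <- as.integer(dom)
  cells1 <- which(domv == 1L); cells2 <- which(domv == 2L)
  glob2loc <- integer(ncell)
  glob2loc[cells1] <- seq_along(cells1)
  glob2loc[cells2] <- seq_along(cells2)

  vol_nm <- as.numeric(outer(outer(dx, dy), dz))  # nm^3, length ncell

  # --- faces -----------------------------------------------------------
  trip <- list(`1` = list(i = list(), j = list(), x = list()),
               `2` = list(i = list(), j = list(), x = list()))
  bf <- list()  # boundary face records

  add_internal <- function(axis) {
    n_axis <- c(nx, ny, nz)[axis]
    if (n_axis < 2) return(invisible())
    idxA <- switch(axis, list(1:(nx - 1), 1:ny, 1:nz),
                   list(1:nx, 1:(ny - 1), 1:nz),
                   list(1:nx, 1:ny, 1:(nz - 1)))
    A <- dom[idxA[[1]], idxA[[2]], idxA[[3]], drop = FALSE]
    idxB <- idxA; idxB[[axis]] <- idxB[[axis]] + 1L
    B <- dom[idxB[[1]], idxB[[2]], idxB[[3]], drop = FALSE]
    # transmissibility area/dist (converted to m)
    cdist <- switch(axis, diff(xc), diff(yc), diff(zc))
    area2 <- switch(axis, outer(dy, dz), outer(dx, dz), outer(dx, dy))
    Tarr <- switch(axis,
      outer(1 / cdist, area2),
      aperm(outer(1 / cdist, outer(dx, dz)), c(2, 1, 3)),
      aperm(outer(1 / cdist, outer(dx, dy)), c(2, 3, 1)))
    Tarr <- Tarr * NM  # (nm^2/nm) -> m
    gidA <- array(seq_len(ncell), dim = c(nx, ny, nz))[idxA[[1]], idxA[[2]], idxA[[3]], drop = FALSE]
    gidB <- array(seq_len(ncell), dim = c(nx, ny, nz))[idxB[[1]], idxB[[2]], idxB[[3]], drop = FALSE]
    for (d in 1:2) {
      m <- which(A == d & B == d)
      if (!length(m)) next
      a <- glob2loc[gidA[m]]; b <- glob2loc[gidB[m]]; t <- Tarr[m]
      tr <- trip[[d]]
      tr$i <- c(tr$i, list(a, b, a, b))
      tr$j <- c(tr$j, list(a, b, b, a))
      tr$x <- c(tr$x, list(t, t, -t, -t))
      trip[[d]] <<- tr
    }
    # membrane faces between the two domains
    m <- which(A != B)
    if (length(m)) {
      sub <- arrayInd(m, dim(A))
      i <- sub[, 1]; j <- sub[, 2]; k <- sub[, 3]
      fc <- switch(axis,
        cbind(xs[i + 1], yc[j], zc[k]),
        cbind(xc[i], ys[j + 1], zc[k]),
        cbind(xc[i], yc[j], zs[k + 1]))
      ar <- switch(axis, dy[j] * dz[k], dx[i] * dz[k], dx[i] * dy[j])
      hw <- switch(axis, cbind(dy[j], dz[k]), cbind(dx[i], dz[k]),
                   cbind(dx[i], dy[j])) / 2
      gA <- gidA[m]; gB <- gidB[m]
      dA <- A[m]  # domain of the "low" cell; outward normal +axis
      for (side in 1:2) {
        g <- if (side == 1) gA else gB
        sgn <- if (side == 1) 1 else -1
        bf[[length(bf) + 1]] <<- data.frame(
          dom = if (side == 1) dA else 3L - dA,
          cell = glob2loc[g], axis = axis, sgn = sgn,
          cx = fc[, 1], cy = fc[, 2], cz = fc[, 3],
          area = ar, h1 = hw[, 1], h2 = hw[, 2],
          type = "membrane", Tb = NA_real_)
      }
    }
    invisible()
  }

  add_boundary <- function(axis, hi) {
    dims <- c(nx, ny, nz)
    idx <- list(1:nx, 1:ny, 1:nz)
    idx[[axis]] <- if (hi) dims[axis] else 1L
    sl <- dom[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    gid <- array(seq_len(ncell), dim = dims)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    m <- seq_along(sl)
    sub <- arrayInd(m, dim(sl))
    ii <- idx[[1]][sub[, 1]]; jj <- idx[[2]][sub[, 2]]; kk <- idx[[3]][sub[, 3]]
    lines <- list(xs, ys, zs)[[axis]]
    bcoord <- if (hi) lines[length(lines)] else lines[1]
    fc <- cbind(xc[ii], yc[jj], zc[kk])
    fc[, axis] <- bcoord
    ar <- switch(axis, dy[jj] * dz[kk], dx[ii] * dz[kk], dx[ii] * dy[jj])
    hw <- switch(axis, cbind(dy[jj], dz[kk]), cbind(dx[ii], dz[kk]),
                 cbind(dx[ii], dy[jj])) / 2
    cc <- switch(axis, xc[ii], yc[jj], zc[kk])
    Tb <- ar / abs(bcoord - cc) * NM
    d <- as.integer(sl[m])
    # types: lateral box faces -> Dirichlet for the cytosol; PM (z=0) and the
    # box bottom outside the cone -> no-flux; ER bottom -> Dirichlet
    type <- rep("noflux", length(m)); surf <- rep("", length(m))
    if (axis <= 2) {
      type[d == 1L] <- "dirichlet"; surf <- rep("lateral", length(m))
    } else if (!hi) {
      surf <- rep("PM", length(m))
    } else {
      type[d == 2L] <- "dirichlet"
      surf <- ifelse(d == 2L, "ER_bulk", "bottom")
    }
    bf[[length(bf) + 1]] <<- data.frame(
      dom = d, cell = glob2loc[gid[m]], axis = axis,
      sgn = if (hi) 1 else -1,
      cx = fc[, 1], cy = fc[, 2], cz = fc[, 3], area = ar,
      h1 = hw[, 1], h2 = hw[, 2], type = type, Tb = Tb, surface = surf)
    invisible()
  }

  for (ax in 1:3) add_internal(ax)
  for (ax in 1:3) for (hi in c(FALSE, TRUE)) add_boundary(ax, hi)

  # label membrane faces (done here so both records exist)
  bf <- lapply(bf, function(df) {
    if (!"surface" %in% names(df)) {
      df$surface <- ifelse(df$axis == 3 & abs(df$cz - geom$gap) < 1e-9,
                           "ER_top", "ER_lateral")
    }
    df
  })
  bfa <- do.call(rbind, bf)
  bfa$Tb[bfa$type != "dirichlet"] <- NA_real_

  # assemble per-domain operators (geometry-only; multiply by D at use)
  Ks <- vector("list", 2)
  bft <- vector("list", 2)
  for (d in 1:2) {
    ndof <- if (d == 1) length(cells1) else length(cells2)
    if (ndof == 0) next  # sub-domain absent (e.g. flat-PM test geometry)
    tr <- trip[[d]]
    ii <- unlist(tr$i); jj <- unlist(tr$j); xx <- unlist(tr$x)
    sub <- bfa[bfa$dom == d, , drop = FALSE]
    dir <- sub[sub$type == "dirichlet", , drop = FALSE]
    if (nrow(dir)) {
      ii <- c(ii, dir$cell); jj <- c(jj, dir$cell); xx <- c(xx, dir$Tb)
    }
    K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
    Ks[[d]] <- Matrix::forceSymmetric(K)
    # face coordinates in metres for all solver-side work
    sub$cx <- sub$cx * NM; sub$cy <- sub$cy * NM; sub$cz <- sub$cz * NM
    sub$area <- sub$area * NM^2; sub$h1 <- sub$h1 * NM; sub$h2 <- sub$h2 * NM
    bft[[d]] <- sub
  }

  m <- structure(list(
    geom = geom, layout = layout, spec = mesh, key = key,
    xs = xs, ys = ys, zs = zs, xc = xc, yc = yc, zc = zc,
    dx = dx, dy = dy, dz = dz, nx = nx, ny = ny, nz = nz,
    ncell = ncell, dom = domv, glob2loc = glob2loc,
    cells = list(cyto = cells1, er = cells2),
    vol = list(cyto = vol_nm[cells1] * NM^3, er = vol_nm[cells2] * NM^3),
    K = list(cyto = Ks[[1]], er = Ks[[2]]),
    bf = list(cyto = bft[[1]], er = bft[[2]])
  ), class = "junction_mesh")

  m$sides <- build_patch_sides(m)
  m <- build_eval_structures(m)
  cache_put(key, m, "mesh")
  m
}

#' @export
print.junction_mesh <- function(x, ...) {
  cat(sprintf(paste0("junction_mesh: %d x %d x %d cells (%d cytosol, %d ER)\n",
                     "  fine spacing %g nm, bulk %g nm\n"),
              x$nx, x$ny, x$nz, length(x$cells$cyto), length(x$cells$er),
              x$spec$target_h_patch, x$spec$target_h_bulk))
  invisible(x)
}

#' Total discretised volume per sub-domain (nm^3)
#'
#' @param mesh a [junction_mesh()].
#' @return named numeric: cytosol and ER volumes (nm^3).
#' @export
mesh_volumes <- function(mesh) {
  c(cyto = sum(mesh$vol$cyto), er = sum(mesh$vol$er)) / NM^3
}

# --- patch-side records ----------------------------------------------------

# analytic inward flux fraction of a unit point kernel 1/(2 pi r) through
# boundary faces; faces coplanar with the point contribute exactly 0
face_phi <- function(bfd, p) {
  dxyz <- cbind(bfd$cx - p[1], bfd$cy - p[2], bfd$cz - p[3])
  comp <- dxyz[cbind(seq_len(nrow(bfd)), bfd$axis)] * bfd$sgn
  r2c <- rowSums(dxyz^2)
  diag2 <- bfd$h1^2 + bfd$h2^2
  phi <- numeric(nrow(bfd))
  flat <- abs(comp) < 1e-18
  far <- !flat & r2c > (6^2) * diag2
  phi[far] <- -(bfd$area[far] / (2 * pi)) * comp[far] / r2c[far]^1.5
  near <- which(!flat & !far)
  if (length(near)) {
    tang <- matrix(c(2, 3, 1, 3, 1, 2), nrow = 3, byrow = TRUE)
    for (nq in c(4L, 8L)) {
      sel <- if (nq == 4L) near[r2c[near] > 2^2 * diag2[near]]
             else near[r2c[near] <= 2^2 * diag2[near]]
      if (!length(sel)) next
      off <- (2 * seq_len(nq) - 1) / nq - 1  # midpoints on [-1, 1]
      o <- expand.grid(a = off, b = off)
      inv3 <- numeric(length(sel))
      t1 <- tang[bfd$axis[sel], 1]; t2 <- tang[bfd$axis[sel], 2]
      for (q in seq_len(nrow(o))) {
        dd <- dxyz[sel, , drop = FALSE]
        dd[cbind(seq_along(sel), t1)] <- dd[cbind(seq_along(sel), t1)] +
          o$a[q] * bfd$h1[sel]
        dd[cbind(seq_along(sel), t2)] <- dd[cbind(seq_along(sel), t2)] +
          o$b[q] * bfd$h2[sel]
        r2 <- rowSums(dd^2)
        inv3 <- inv3 + ifelse(r2 < 1e-30, 0, 1 / r2^1.5)
      }
      phi[sel] <- -(bfd$area[sel] / (2 * pi)) * comp[sel] * inv3 / nrow(o)
    }
  }
  phi
}

patch_host_surface <- function(kind, domain) {
  if (kind == "ORAI") "PM"
  else if (kind == "SERCA") "ER_top"
  else c("ER_lateral", "ER_top")
}

build_patch_sides <- function(m) {
  hf <- m$spec$target_h_patch * NM
  sides <- list()
  for (p in m$layout) {
    doms <- switch(p$kind, ORAI = "cyto", IP3R = c("cyto", "er"),
                   SERCA = c("cyto", "er"))
    sgns <- switch(p$kind, ORAI = 1, IP3R = c(1, -1), SERCA = c(-1, 1))
    for (s in seq_along(doms)) {
      d <- doms[s]
      bfd <- m$bf[[d]]
      host <- bfd$surface %in% patch_host_surface(p$kind, d)
      if (!any(host)) mesh_resolution_error(
        "no host boundary faces for patch %s#%d in %s", p$kind, p$index, d)
      hostidx <- which(host)
      hc <- bfd[hostidx, ]
      pt <- p$center * NM
      dist <- sqrt((hc$cx - pt[1])^2 + (hc$cy - pt[2])^2 + (hc$cz - pt[3])^2)
      nearest <- which.min(dist)
      if (dist[nearest] > p$radius * NM + 2 * hf)
        mesh_resolution_error(
          "patch %s#%d lies %.3g nm from the nearest %s boundary face",
          p$kind, p$index, dist[nearest] / NM, d)
      # snap the kernel point onto the discrete boundary: exact for patches
      # on flat grid-aligned planes (PM, ER top face), nearest-face centre on
      # the stair-stepped cone wall
      point <- if (p$surface %in% c("PM", "ER_top_face")) pt
               else c(hc$cx[nearest], hc$cy[nearest], hc$cz[nearest])
      foot <- which(dist <= pmax(p$radius * NM, 0.8 * hf))
      if (!length(foot)) foot <- nearest
      wfoot <- hc$area[foot] / sum(hc$area[foot])
      # compensation (unit molar rate): Neumann faces cancel the kernel flux,
      # Dirichlet faces pin the total field
      neum <- bfd$type != "dirichlet"
      phi <- face_phi(bfd[neum, , drop = FALSE], point)
      dirf <- bfd[bfd$type == "dirichlet", , drop = FALSE]
      rdir <- sqrt((dirf$cx - point[1])^2 + (dirf$cy - point[2])^2 +
                     (dirf$cz - point[3])^2)
      gdir <- 1 / (2 * pi * rdir)
      bidx <- c(bfd$cell[neum], dirf$cell)
      bval <- c(-phi, -dirf$Tb * gdir)
      bvec <- rowsum(bval, bidx)
      sides[[length(sides) + 1]] <- list(
        kind = p$kind, index = p$index, domain = d, sgn = sgns[s],
        point = point, a = p$radius * NM, area = p$area * NM^2,
        eval_cell = hc$cell[nearest],
        host_rows = hostidx[foot], host_w = wfoot,
        bidx = as.integer(rownames(bvec)), bval = as.numeric(bvec),
        gdir = gdir, phi_dir = -sum(face_phi(dirf, point)),
        coef_center = 1 / (pi * p$radius * NM),
        coef_avg = (8 / (3 * pi^2)) / (p$radius * NM))
    }
  }
  sides
}

# --- evaluation structures ---------------------------------------------------

side_index <- function(m, domain, kind = NULL) {
  sel <- vapply(m$sides, function(s) s$domain == domain &&
                  (is.null(kind) || s$kind == kind), TRUE)
  which(sel)
}

build_eval_structures <- function(m) {
  geom <- m$geom
  # cross-influence between patch points within each domain: coefficient of
  # Q/D on the concentration at side i's point due to side j's kernel
  for (d in c("cyto", "er")) {
    idx <- side_index(m, d)
    n <- length(idx)
    G <- matrix(0, n, n)
    if (n > 1) {
      P <- t(vapply(m$sides[idx], function(s) s$point, numeric(3)))
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        r <- sqrt(sum((P[i, ] - P[j, ])^2))
        G[i, j] <- 1 / (2 * pi * r)
      }
    }
    m[[paste0("G_", d)]] <- G
    m[[paste0("sides_", d)]] <- idx
  }

  # junction-cylinder quadrature (analytic part) and cell weights (w part)
  Rj <- geom$junction_radius * NM
  gz <- geom$gap * NM
  nrq <- 40L; ntq <- 48L; nzq <- 6L
  rq <- (seq_len(nrq) - 0.5) / nrq * Rj
  tq <- (seq_len(ntq) - 0.5) / ntq * 2 * pi
  zq <- (seq_len(nzq) - 0.5) / nzq * gz
  qg <- expand.grid(r = rq, t = tq, z = zq)
  jpts <- cbind(qg$r * cos(qg$t), qg$r * sin(qg$t), qg$z)
  jw <- qg$r  # dV = r dr dt dz with uniform spacing
  jw <- jw / sum(jw)
  gjun <- vapply(m$sides_cyto, function(si) {
    s <- m$sides[[si]]
    r <- sqrt(colSums((t(jpts) - s$point)^2))
    sum(jw / (2 * pi * pmax(r, 1e-12)))
  }, 0)
  gxc <- m$xc[arrayInd(m$cells$cyto, c(m$nx, m$ny, m$nz))[, 1]]
  gyc <- m$yc[arrayInd(m$cells$cyto, c(m$nx, m$ny, m$nz))[, 2]]
  gzc <- m$zc[arrayInd(m$cells$cyto, c(m$nx, m$ny, m$nz))[, 3]]
  injun <- (gxc^2 + gyc^2 < geom$junction_radius^2) & (gzc < geom$gap)
  m$junction <- list(g = gjun, cells = which(injun),
                     w = m$vol$cyto[injun] / sum(m$vol$cyto[injun]),
                     volume = junction_volume(geom) * NM^3)

  # sensing-cube quadrature per IP3R (ER side)
  ip3r_er <- side_index(m, "er", "IP3R")
  cubes <- list()
  if (length(ip3r_er)) {
    sub <- arrayInd(m$cells$er, c(m$nx, m$ny, m$nz))
    exc <- m$xc[sub[, 1]]; eyc <- m$yc[sub[, 2]]; ezc <- m$zc[sub[, 3]]
    for (si in ip3r_er) {
      s <- m$sides[[si]]
      reg <- sensing_region(m$layout, s$index, geom)
      qq <- sensing_quadrature(reg, geom, n = 16)
      pts <- qq$points[qq$inside, , drop = FALSE] * NM
      gcube <- vapply(m$sides_er, function(sj) {
        sj <- m$sides[[sj]]
        r <- sqrt(colSums((t(pts) - sj$point)^2))
        mean(1 / (2 * pi * pmax(r, 1e-12)))
      }, 0)
      incube <- exc >= reg$lower[1] & exc <= reg$upper[1] &
        eyc >= reg$lower[2] & eyc <= reg$upper[2] &
        ezc >= reg$lower[3] & ezc <= reg$upper[3]
      wcell <- m$vol$er[incube]
      cubes[[s$index]] <- list(g = gcube, cells = which(incube),
                               w = wcell / sum(wcell))
    }
  }
  m$cubes <- cubes
  m
}

# cached Cholesky factor of the geometry-only operator
mesh_factor <- function(m, domain) {
  fkey <- paste0(m$key, "#factor_", domain)
  f <- cache_get(fkey)
  if (is.null(f)) {
    K <- m$K[[domain]]
    if (is.null(K)) return(NULL)
    # make room before factorising: supernodal factors of the 3D operator
    # run to roughly 7 kB per unknown
    est <- 7000 * nrow(K)
    cache_trim("factor", max(cache_budget("factor") - est, 0))
    f <- Matrix::Cholesky(K, LDL = FALSE, super = TRUE)
    cache_put(fkey, f, "factor")
  }
  f
}
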