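test_that("junction and cone volumes match their closed forms", {
  g <- junction_geometry()
  expect_equal(junction_volume(g), pi * 100^2 * 15)
  expect_equal(junction_volume(g), 4.712389e5, tolerance = 1e-6)
  R <- 200; r <- 100
  expect_equal(cone_volume(g), pi * 485 / 3 * (R^2 + R * r + r^2))
  expect_equal(cone_volume(g), 3.5552e7, tolerance = 1e-4)
  expect_equal(g$total_height, g$gap + g$cone_depth)
})

test_that("ring positions follow the chord spacing formula", {
  expect_equal(attr(ring_positions(5, 40), "spacing"), 47.0, tolerance = 1e-3)
  expect_equal(attr(ring_positions(10, 70), "spacing"), 43.3, tolerance = 1e-3)
  expect_true(is.na(attr(ring_positions(1, 40), "spacing")))
  for (n in 2:12) {
    p <- ring_positions(n, 55, z = 3)
    d <- sqrt(sum((p[1, ] - p[2, ])^2))
    expect_equal(d, 2 * 55 * sin(pi / n), tolerance = 1e-12)
    expect_equal(attr(p, "spacing"), d, tolerance = 1e-12)
  }
  expect_error(ring_positions(0, 40), class = "socesim_invalid_argument")
  expect_error(ring_positions(3, -1), class = "socesim_invalid_argument")
})

test_that("default layout is invariant under 72-degree rotation", {
  lay <- channel_layout(junction_geometry())
  orai <- t(vapply(Filter(function(p) p$kind == "ORAI", unclass(lay)),
                   function(p) p$center, numeric(3)))
  th <- 2 * pi / 5
  rot <- cbind(orai[, 1] * cos(th) - orai[, 2] * sin(th),
               orai[, 1] * sin(th) + orai[, 2] * cos(th))
  perm <- c(2, 3, 4, 5, 1)
  expect_lt(max(abs(rot - orai[perm, 1:2])), 1e-9)
})

test_that("IP3R ring follows the cone's linear taper", {
  g <- junction_geometry()
  ip <- ip3r_positions(g, 8, 90)
  expect_equal(attr(ip, "ring_radius"), 100 + 100 * (90 - 15) / 485,
               tolerance = 1e-12)
  expect_equal(attr(ip, "ring_radius"), 115.46, tolerance = 1e-4)
  expect_equal(attr(ip, "spacing"), 2 * 115.4639 * sin(pi / 8),
               tolerance = 1e-5)
  expect_equal(attr(ip, "spacing"), 88.37, tolerance = 1e-3)
  # taper endpoints
  expect_equal(cone_radius_at(g, 15), 100)
  expect_equal(cone_radius_at(g, 500), 200)
  expect_true(is.na(cone_radius_at(g, 600)))
  expect_error(ip3r_positions(g, 8, 600),
               class = "socesim_geometry_violation")
  expect_error(ip3r_positions(g, 8, 15),
               class = "socesim_geometry_violation")
})

test_that("each ORAI is associated with its nearest IP3R", {
  lay <- channel_layout(junction_geometry())
  map <- attr(lay, "orai_to_ip3r")
  orai <- Filter(function(p) p$kind == "ORAI", unclass(lay))
  ip3r <- Filter(function(p) p$kind == "IP3R", unclass(lay))
  # brute force over all pairs
  for (k in seq_along(orai)) {
    d <- vapply(ip3r, function(q) sqrt(sum((orai[[k]]$center - q$center)^2)), 0)
    expect_equal(map[k], which.min(d))
    expect_true(all(d[map[k]] <= d))
  }
  # a channel equidistant from all receptors maps to the lowest index
  lay1 <- channel_layout(junction_geometry(), n_orai = 1,
                         orai_ring_radius = 0)
  expect_identical(attr(lay1, "orai_to_ip3r"), 1L)
})

test_that("sensing regions: interior cube exact, wall cube clipped", {
  g <- junction_geometry()
  lay <- channel_layout(g)
  reg <- sensing_region(lay, 1, g)
  expect_equal(reg$edge, 108)
  v <- sensing_volume(reg, g, n = 50)
  expect_lt(v, 108^3)           # clipped by the cone wall
  expect_gt(v, 0.3 * 108^3)
  # a cube fully inside the ER integrates to its exact volume
  interior <- structure(list(center = c(0, 0, 300), edge = 50,
                             lower = c(-25, -25, 275),
                             upper = c(25, 25, 325)),
                        class = "sensing_region")
  expect_equal(sensing_volume(interior, g, n = 20), 50^3)
  expect_error(sensing_region(lay, 99, g),
               class = "socesim_invalid_argument")
  expect_error(channel_layout(g, sensing_edge = 0),
               class = "socesim_invalid_argument")
})

test_that("geometry invariants are enforced", {
  expect_error(junction_geometry(gap = 0),
               class = "socesim_geometry_violation")
  expect_error(junction_geometry(cone_top_radius = 300),
               class = "socesim_geometry_violation")
  expect_error(junction_geometry(cone_bottom_radius = 250, box_side = 400),
               class = "socesim_geometry_violation")
  # overlapping patches on the same surface are rejected
  expect_error(channel_layout(junction_geometry(), n_orai = 2,
                              orai_ring_radius = 0),
               class = "socesim_geometry_violation")
})

test_that("layout manifest lists every patch with its sensing association", {
  lay <- channel_layout(junction_geometry())
  path <- tempfile(fileext = ".tsv")
  tab <- write_layout_manifest(lay, path)
  expect_true(file.exists(path))
  back <- read.delim(path)
  expect_equal(nrow(back), 5 + 10 + 8)
  expect_equal(back$senses_ip3r[back$kind == "ORAI"],
               as.integer(attr(lay, "orai_to_ip3r")))
  expect_true(all(c("kind", "index", "x", "y", "z", "radius", "surface")
                  %in% names(back)))
})
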