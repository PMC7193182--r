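test_that("normal geometry carries the anatomical duct and closes the loop", {
  geom <- make_normal_geometry()
  duct <- geom$segments[geom$segments$name == "duct", ]
  expect_equal(2 * duct$lumen_radius, 0.45)
  expect_equal(sum(geom$segments$subtended_angle), 2 * pi, tolerance = 1e-12)
  expect_identical(geom$hydrops_state, "none")

  # the utricle absorbs whatever angle the duct and ampulla leave over
  geom2 <- make_normal_geometry(geometry_config(duct_angle_rad = 4.6,
                                                ampulla_angle_rad = 0.2))
  other <- sum(geom2$segments$subtended_angle[geom2$segments$name != "duct"])
  expect_equal(other, 2 * pi - 4.6, tolerance = 1e-12)
})

test_that("invalid configurations are rejected with validation errors", {
  expect_error(make_normal_geometry(geometry_config(duct_diameter_mm = -1)),
               class = "vestsim_error_validation")
  expect_error(make_normal_geometry(geometry_config(duct_angle_rad = 0)),
               class = "vestsim_error_validation")
  expect_error(make_normal_geometry(geometry_config(duct_angle_rad = 6.2,
                                                    ampulla_angle_rad = 0.2)),
               class = "vestsim_error_validation")
  expect_error(geometry_config(not_a_key = 1), class = "vestsim_error_validation")
  # self-intersecting loop: lumen radius exceeding the centerline radius
  expect_error(
    labyrinth_geometry(0.5, tibble::tibble(
      name = "duct", subtended_angle = 2 * pi, lumen_radius = 0.6
    )),
    class = "vestsim_error_validation"
  )
})

test_that("canal hydrops dilates the duct and respects the osseous limit", {
  geom <- make_normal_geometry()
  hyd <- apply_canal_hydrops(geom, 1.3 / 0.45)
  duct <- hyd$segments[hyd$segments$name == "duct", ]
  expect_equal(2 * duct$lumen_radius, 1.3)
  expect_identical(hyd$hydrops_state, "canal")
  # all other segments untouched
  expect_equal(hyd$segments[hyd$segments$name != "duct", ],
               geom$segments[geom$segments$name != "duct", ])

  same <- apply_canal_hydrops(geom, 1)
  expect_equal(same$segments, geom$segments)
  expect_identical(same$hydrops_state, "canal")

  err <- expect_error(apply_canal_hydrops(geom, 4),
                      class = "vestsim_error_constraint")
  expect_match(conditionMessage(err), "1.53")
  expect_error(apply_canal_hydrops(geom, 0.5), class = "vestsim_error_validation")
  expect_error(apply_canal_hydrops(hyd, 2), class = "vestsim_error_validation")
})

test_that("utricular hydrops dilates only the utricle", {
  geom <- make_normal_geometry()
  hyd <- apply_utricular_hydrops(geom, 3)
  expect_equal(hyd$segments$lumen_radius[hyd$segments$name == "utricle"],
               3 * geom$segments$lumen_radius[geom$segments$name == "utricle"])
  expect_equal(hyd$segments$lumen_radius[hyd$segments$name == "duct"],
               geom$segments$lumen_radius[geom$segments$name == "duct"])
  expect_identical(hyd$hydrops_state, "utricular")

  expect_equal(apply_utricular_hydrops(geom, 1)$segments, geom$segments)
  expect_error(apply_utricular_hydrops(geom, -3), class = "vestsim_error_validation")
})

test_that("enclosed areas match their closed forms", {
  uniform <- all_duct_geometry(R = 3.2, lumen = 0.225)
  expect_equal(enclosed_area(uniform, "middle"), pi * 3.2^2, tolerance = 1e-12)
  expect_equal(enclosed_area(uniform, "outer"), pi * 3.425^2, tolerance = 1e-12)

  # two-segment piecewise path, hand-evaluated polar closed form
  two <- labyrinth_geometry(3.2, tibble::tibble(
    name = c("duct", "utricle"),
    subtended_angle = c(4.6, 2 * pi - 4.6),
    lumen_radius = c(0.225, 0.60)
  ))
  expected <- 0.5 * (4.6 * (3.2 + 0.225)^2 + (2 * pi - 4.6) * (3.2 + 0.60)^2)
  expect_equal(enclosed_area(two, "outer"), expected, tolerance = 1e-12)
})

test_that("enclosed_area agrees with 1e5-vertex polygonal quadrature", {
  for (geom in default_geometries()) {
    expect_equal(enclosed_area(geom, "outer"), polygon_outer_area(geom),
                 tolerance = 1e-6)
  }
})

test_that("outer area is strictly monotone in lumen radii; middle is invariant", {
  base <- make_normal_geometry()
  a_mid <- enclosed_area(base, "middle")
  a_out <- enclosed_area(base, "outer")
  expect_gt(a_out, a_mid)
  for (seg in c("duct", "utricle", "ampulla")) {
    bigger <- base
    bigger$segments$lumen_radius[bigger$segments$name == seg] <-
      bigger$segments$lumen_radius[bigger$segments$name == seg] + 0.05
    bigger <- labyrinth_geometry(base$centerline_radius, bigger$segments,
                                 osseous_canal_diameter = 10)
    expect_gt(enclosed_area(bigger, "outer"), a_out)
    expect_equal(enclosed_area(bigger, "middle"), a_mid)
  }
})

test_that("STL export produces a watertight torus-topology mesh that round-trips", {
  geom <- make_normal_geometry()
  n_theta <- 96
  n_phi <- 20
  f_bin <- withr::local_tempfile(fileext = ".stl")
  f_asc <- withr::local_tempfile(fileext = ".stl")
  n_facets <- export_stl(geom, f_bin, n_theta = n_theta, n_phi = n_phi)
  export_stl(geom, f_asc, n_theta = n_theta, n_phi = n_phi, ascii = TRUE)
  expect_identical(as.integer(n_facets), as.integer(2 * n_theta * n_phi))

  bin <- read_stl(f_bin)
  asc <- read_stl(f_asc)
  expect_identical(bin$n_facets, as.integer(2 * n_theta * n_phi))
  expect_identical(asc$n_facets, bin$n_facets)
  # binary stores float32; ASCII full precision - agreement to float tolerance
  expect_equal(as.matrix(bin$facets), as.matrix(asc$facets), tolerance = 1e-6)

  # Euler characteristic of a closed tube (torus): V - E + F = 0
  verts <- round(as.matrix(bin$facets), 4)
  key <- apply(verts, 1, paste, collapse = "/")
  vid <- match(key, unique(key))
  tris <- matrix(vid, ncol = 3, byrow = TRUE)
  edges <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  edges <- unique(t(apply(edges, 1, sort)))
  V <- length(unique(vid))
  E <- nrow(edges)
  F <- nrow(tris)
  expect_identical(V - E + F, 0L)
  # every edge is shared by exactly two facets (watertight)
  expect_identical(3L * F, 2L * E)

  # outward normals: positive flux through the surface at facet centroids
  centroids <- (as.matrix(bin$facets)[seq(1, 3 * F, 3), ] +
                as.matrix(bin$facets)[seq(2, 3 * F, 3), ] +
                as.matrix(bin$facets)[seq(3, 3 * F, 3), ]) / 3
  axis_dist <- sqrt(centroids[, 1]^2 + centroids[, 2]^2)
  ring <- cbind(
    geom$centerline_radius * centroids[, 1] / axis_dist,
    geom$centerline_radius * centroids[, 2] / axis_dist,
    0
  )
  outward <- centroids - ring
  dots <- rowSums(as.matrix(bin$normals) * outward)
  expect_true(all(dots > 0))

  expect_error(export_stl(geom, file.path(tempdir(), "no-such-dir", "x.stl")),
               class = "vestsim_error_io")
})
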