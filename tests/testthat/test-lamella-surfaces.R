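planar_geometry <- function(front = 200, back = 300, tilt = 6, seed = 1) {
  make_lamella_geometry(thickness_front = front, thickness_back = back,
                        tilt = tilt, jitter_sd = 0, seed = seed)
}

test_that("interpolated heights reproduce an exactly digitised planar slab", {
  geo <- planar_geometry()
  s <- interpolate_surfaces(geo$model)
  g <- expand.grid(x = seq(0, 2000, by = 137), y = seq(0, 2000, by = 211))
  expect_equal(surface_height(s, "top", g$x, g$y), geo$truth$top(g$x, g$y),
               tolerance = 1e-9)
  expect_equal(surface_height(s, "bottom", g$x, g$y), geo$truth$bottom(g$x, g$y),
               tolerance = 1e-9)
})

test_that("evaluation outside the digitised range clamps to the boundary", {
  geo <- planar_geometry()
  s <- interpolate_surfaces(geo$model)
  expect_equal(surface_height(s, "top", -500, -500),
               surface_height(s, "top", 0, 0))
  expect_equal(surface_height(s, "top", 99999, 99999),
               surface_height(s, "top", 2000, 2000))
})

test_that("normal thickness removes the tilt inflation of the axial gap", {
  geo <- planar_geometry(front = 200, back = 200, tilt = 10)
  s <- interpolate_surfaces(geo$model)
  sf <- sqrt(1 + tan(10 * pi / 180)^2)
  expect_equal(tomogram_thickness(s, "axial"), 200 * sf, tolerance = 1e-6)
  expect_equal(tomogram_thickness(s, "normal"), 200, tolerance = 1e-6)
  # untilted slab: the two coincide
  geo0 <- planar_geometry(front = 250, back = 250, tilt = 0)
  s0 <- interpolate_surfaces(geo0$model)
  expect_equal(tomogram_thickness(s0, "axial"), tomogram_thickness(s0, "normal"),
               tolerance = 1e-9)
})

test_that("nearest-surface distances match the analytic truth on planar sheets", {
  geo <- planar_geometry(front = 180, back = 320, tilt = 8)
  smp <- sample_particles(geo, 300, seed = 3)
  s <- interpolate_surfaces(geo$model)
  d <- distance_to_nearest_surface(s, smp$particles$x, smp$particles$y,
                                   smp$particles$z)
  expect_equal(d$distance_nm, smp$truth$true_depth_nm, tolerance = 0.05)
  expect_true(all(d$side %in% c("top", "bottom")))
  expect_false(any(d$out_of_footprint))
  out <- distance_to_nearest_surface(s, -100, -100, 0)
  expect_true(out$out_of_footprint)
})

test_that("annotation fills depth and thickness and is idempotent", {
  geo <- planar_geometry()
  smp <- sample_particles(geo, 50, seed = 4)
  s <- interpolate_surfaces(geo$model)
  ann1 <- annotate_particles(smp$particles, s)
  expect_true(all(c("depth_nm", "tomo_thickness_nm", "out_of_footprint") %in%
                    names(ann1)))
  expect_true(all(ann1$depth_nm >= 0))
  ann2 <- annotate_particles(ann1, s)
  expect_equal(ann1, ann2)
})

test_that("annotation requires a surface model for every tomogram", {
  geo <- planar_geometry()
  smp <- sample_particles(geo, 5, seed = 5)
  s <- interpolate_surfaces(geo$model)
  stray <- smp$particles
  stray$tomogram_id <- "unmodelled_tomo"
  expect_error(annotate_particles(stray, s), class = "lamellar_validation_error")
  # multi-tomogram dispatch by id
  geo2 <- make_lamella_geometry(tomogram_id = "second", jitter_sd = 0)
  smp2 <- sample_particles(geo2, 5, seed = 6)
  both <- dplyr::bind_rows(smp$particles, smp2$particles)
  ann <- annotate_particles(both, list(s, interpolate_surfaces(geo2$model)))
  expect_equal(nrow(ann), 10)
  expect_false(anyNA(ann$depth_nm))
})

test_that("thickness summaries report mean, sample sd, median and n", {
  s <- thickness_summary(c(240, 250, 260))
  expect_equal(s$mean, 250)
  expect_equal(s$sd, sd(c(240, 250, 260)))
  expect_equal(s$median, 250)
  expect_equal(s$n, 3L)
  one <- thickness_summary(245)
  expect_equal(one$sd, 0)
  expect_error(thickness_summary(NA_real_), class = "lamellar_domain_error")
})

test_that("particle-weighted thickness pools datasets by particle count", {
  # three cohorts: 180 particles at 250 nm, 30 at 227 nm, 47 at 245 nm
  counts <- c(180, 30, 47)
  values <- c(250, 227, 245)
  t <- tibble::tibble(
    particle_id = sprintf("p%04d", seq_len(sum(counts))),
    tomogram_id = rep(c("a", "b", "c"), counts),
    x = 0, y = 0, z = 0,
    tomo_thickness_nm = rep(values, counts)
  )
  w <- weighted_average_thickness(t)
  expect_equal(w$mean, sum(counts * values) / sum(counts))
  expect_equal(w$mean, 246.4, tolerance = 1e-3)
  expect_equal(w$n, 257L)
  expect_error(weighted_average_thickness(t[, 1:5]),
               class = "lamellar_validation_error")
})

test_that("thickness-vs-edge regression recovers a known linear trend", {
  # residuals orthogonal to the design: OLS recovers slope/intercept exactly
  pts <- data.frame(edge_distance = c(1, 2, 3, 4, 5),
                    thickness = 200 + 12.5 * c(1, 2, 3, 4, 5) +
                      c(1, -2, 0, 2, -1))
  tr <- thickness_vs_edge_regression(pts)
  expect_equal(tr$slope, 12.5, tolerance = 1e-9)
  expect_equal(tr$intercept, 200, tolerance = 1e-9)
  expect_true(all(tr$band$lwr <= tr$band$fit & tr$band$fit <= tr$band$upr))
  gl <- generics::glance(tr)
  expect_equal(gl$n, 5L)
  expect_gt(gl$r.squared, 0.99)
  expect_error(thickness_vs_edge_regression(pts[1:2, ]),
               class = "lamellar_domain_error")
  flat <- data.frame(edge_distance = c(1, 1, 1), thickness = c(1, 2, 3))
  expect_error(thickness_vs_edge_regression(flat), class = "lamellar_domain_error")
})
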