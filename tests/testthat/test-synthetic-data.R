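test_that("the damage model ramps linearly from surface excess to bulk", {
  dm <- damage_model(b_bulk = 450, b_surface_excess = 2000, damage_depth = 40)
  expect_equal(effective_bfactor(dm, 0), 2450)
  expect_equal(effective_bfactor(dm, 20), 1450)
  expect_equal(effective_bfactor(dm, 40), 450)
  expect_equal(effective_bfactor(dm, 100), 450)
  expect_equal(effective_bfactor(dm, c(0, 40)), c(2450, 450))
  expect_error(damage_model(damage_depth = 0), class = "lamellar_domain_error")
  expect_error(effective_bfactor(dm, -1), class = "lamellar_domain_error")
})

test_that("lamella geometries carry an exact analytic truth", {
  geo <- make_lamella_geometry(thickness_front = 200, thickness_back = 350,
                               tilt = 8, jitter_sd = 0)
  tr <- geo$truth
  expect_equal(tr$thickness(0), 200)
  expect_equal(tr$thickness(2000), 350)
  expect_equal(tr$thickness(1000), 275)
  # the axial gap is inflated so normal thickness equals the request
  sf <- sqrt(1 + tan(8 * pi / 180)^2)
  expect_equal(tr$top(500, 0) - tr$bottom(500, 0), 200 * sf)
  # 2000 nm extent at 250 nm plane spacing -> 9 contour planes
  expect_equal(length(unique(geo$model$points$plane)), 9L)
  expect_s3_class(geo$model, "boundary_model")
})

test_that("geometry jitter is seeded and bounded validation still applies", {
  g1 <- make_lamella_geometry(jitter_sd = 2, seed = 5)
  g2 <- make_lamella_geometry(jitter_sd = 2, seed = 5)
  g3 <- make_lamella_geometry(jitter_sd = 2, seed = 6)
  expect_equal(g1$model$points$z, g2$model$points$z)
  expect_false(identical(g1$model$points$z, g3$model$points$z))
  expect_error(make_lamella_geometry(extent = c(-1, 100)),
               class = "lamellar_domain_error")
})

test_that("sampled particles respect the margin and record true depths", {
  geo <- make_lamella_geometry(thickness_front = 150, thickness_back = 280,
                               tilt = -6, jitter_sd = 0)
  smp <- sample_particles(geo, 500, margin = 5, seed = 2)
  expect_equal(nrow(smp$particles), 500)
  expect_true(all(smp$truth$true_depth_nm >= 5 - 1e-9))
  expect_true(all(smp$truth$true_depth_nm <= 280 / 2 + 1e-9))
  again <- sample_particles(geo, 500, margin = 5, seed = 2)
  expect_equal(smp$particles, again$particles)
  expect_error(sample_particles(geo, 10, margin = 80),
               class = "lamellar_domain_error")
  none <- sample_particles(geo, 0)
  expect_equal(nrow(none$particles), 0)
})

test_that("depths are uniform through a flat slab", {
  geo <- make_lamella_geometry(thickness_front = 200, thickness_back = 200,
                               tilt = 0, jitter_sd = 0)
  smp <- sample_particles(geo, 20000, margin = 0, seed = 10)
  ks <- suppressWarnings(
    ks.test(smp$truth$true_depth_nm, "punif", min = 0, max = 100)
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("reference volumes are deterministic, cubic and envelope-bounded", {
  ref <- make_reference_volume(box = 32, voxel = 1.9, n_blobs = 20, seed = 3)
  expect_equal(dim(ref$data), c(32, 32, 32))
  expect_equal(ref$data[1, 1, 1], 0) # corner lies outside the envelope
  expect_gt(max(ref$data), 0)
  again <- make_reference_volume(box = 32, voxel = 1.9, n_blobs = 20, seed = 3)
  expect_equal(ref$data, again$data)
  expect_error(make_reference_volume(box = 16), class = "lamellar_domain_error")
})

test_that("noise-free sub-volumes equal the B-attenuated reference", {
  ref <- make_reference_volume(box = 32, seed = 4)
  dm <- damage_model(450, 2000, 40)
  deep <- toy_particles(100)[1, ] # depth 100 nm -> bulk B only
  sim <- simulate_subvolumes(ref, deep, dm, noise_sd = 0)
  expect_equal(sim$truth$bfactor, 450)
  expect_equal(sim$volumes[[1]]$data, attenuate_bfactor(ref, 450)$data,
               tolerance = 1e-8)
  expect_error(simulate_subvolumes(ref, toy_particles(1)[, 1:5], dm),
               class = "lamellar_validation_error")
})

test_that("closed-form half-maps equal averaged per-particle simulations", {
  ref <- make_reference_volume(box = 32, seed = 5)
  dm <- damage_model(450, 2000, 40)
  parts <- toy_particles(c(2, 8, 17, 33, 52, 70))
  sub <- simulate_subvolumes(ref, parts, dm, noise_sd = 0)
  manual <- half_set_average(sub$volumes, split_seed = 9)
  direct <- simulate_damaged_half_maps(ref, parts, dm, noise_sd = 0,
                                       split_seed = 9)
  expect_equal(direct$half1$data, manual$half1$data, tolerance = 1e-8)
  expect_equal(direct$half2$data, manual$half2$data, tolerance = 1e-8)
  expect_error(simulate_damaged_half_maps(ref, parts[1, ], dm),
               class = "lamellar_domain_error")
})

test_that("milling measurement sets are charge-consistent and seeded", {
  sim <- simulate_milling_measurements(true_rate = 4.3, noise_frac = 0,
                                       seed = 1)
  m <- sim$measurements
  expect_equal(sim$truth$volume_um3, 4.3 * m$current * m$mill_time)
  # with zero noise the geometry inverts exactly
  expect_equal(parallelepiped_volume(m), sim$truth$volume_um3, tolerance = 1e-9)
  noisy1 <- simulate_milling_measurements(4.3, seed = 2)
  noisy2 <- simulate_milling_measurements(4.3, seed = 2)
  expect_equal(noisy1$measurements$z_m, noisy2$measurements$z_m)
  expect_false(identical(noisy1$measurements$z_m, m$z_m))
  # only the depth-direction distance carries measurement noise
  expect_equal(noisy1$measurements$b_m, m$b_m)
  expect_error(simulate_milling_measurements(-1), class = "lamellar_domain_error")
})

test_that("resolution curves lie exactly on the Rosenthal-Henderson line", {
  curve <- simulate_resolution_curve(478)
  y <- 1 / curve$d^2
  fit <- lm(y ~ log(curve$n))
  expect_equal(unname(coef(fit)[2]), 2 / 478, tolerance = 1e-9)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-12)
  # default intercept anchors the worst point at 20 Angstrom
  expect_equal(curve$d[which.min(curve$n)], 20, tolerance = 1e-9)
  noisy <- simulate_resolution_curve(478, rel_noise_d = 0.02, seed = 3)
  expect_false(identical(noisy$d, curve$d))
  expect_error(simulate_resolution_curve(478, n_values = c(1, 10)),
               class = "lamellar_domain_error")
})
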