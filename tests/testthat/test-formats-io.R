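test_that("STAR particle tables round-trip losslessly including annotations", {
  t <- tibble::tibble(
    particle_id = sprintf("p%03d", 1:5),
    tomogram_id = c("tomo_a", "tomo_a", "tomo_b", "tomo_b", "tomo_b"),
    x = c(10.25, 333.125, 1.5, 987.654321, 0.0001),
    y = c(20.5, 444.25, 2.5, 123.456789, 1500),
    z = c(30.75, 55.5, 3.5, 42.0, 77.7),
    depth_nm = c(1.25, 14.9, 15, 59.999, 120),
    tomo_thickness_nm = rep(245.5, 5),
    rlnRandomSubset = c("1", "2", "1", "2", "1")
  )
  path <- withr::local_tempfile(fileext = ".star")
  write_particle_star(t, path, pixel_size = 1.9)
  back <- read_particle_star(path, pixel_size = 1.9)
  expect_equal(back$particle_id, t$particle_id)
  expect_equal(back$tomogram_id, t$tomogram_id)
  expect_equal(back$x, t$x, tolerance = 1e-9)
  expect_equal(back$y, t$y, tolerance = 1e-9)
  expect_equal(back$z, t$z, tolerance = 1e-9)
  expect_equal(back$depth_nm, t$depth_nm, tolerance = 1e-9)
  expect_equal(back$tomo_thickness_nm, t$tomo_thickness_nm, tolerance = 1e-9)
  expect_equal(back$rlnRandomSubset, t$rlnRandomSubset)
})

test_that("STAR coordinates are converted px -> nm with the pixel size", {
  path <- withr::local_tempfile(fileext = ".star")
  writeLines(c(
    "data_particles", "", "loop_",
    "_rlnCoordinateX #1", "_rlnCoordinateY #2", "_rlnCoordinateZ #3",
    "_rlnMicrographName #4",
    "100 200 300 tomo_1"
  ), path)
  t <- read_particle_star(path, pixel_size = 1.9)
  # nm = px * (angstrom per px) / 10
  expect_equal(t$x, 100 * 1.9 / 10)
  expect_equal(t$y, 200 * 1.9 / 10)
  expect_equal(t$z, 300 * 1.9 / 10)
  expect_equal(t$tomogram_id, "tomo_1")
  expect_match(t$particle_id, "^p")
})

test_that("STAR parse errors carry file, column and row context", {
  path <- withr::local_tempfile(fileext = ".star")
  writeLines(c(
    "data_particles", "", "loop_",
    "_rlnCoordinateX #1", "_rlnCoordinateY #2", "_rlnCoordinateZ #3",
    "_rlnMicrographName #4",
    "1.0 2.0 3.0 tomo_1",
    "oops 2.0 3.0 tomo_1"
  ), path)
  err <- expect_error(read_particle_star(path, pixel_size = 1),
                      class = "lamellar_parse_error")
  expect_match(conditionMessage(err), "rlnCoordinateX")
  expect_match(conditionMessage(err), "row 2")

  bad_fields <- withr::local_tempfile(fileext = ".star")
  writeLines(c(
    "data_particles", "", "loop_",
    "_rlnCoordinateX #1", "_rlnCoordinateY #2",
    "1.0 2.0 3.0"
  ), bad_fields)
  expect_error(read_particle_star(bad_fields, pixel_size = 1),
               class = "lamellar_parse_error")

  no_loop <- withr::local_tempfile(fileext = ".star")
  writeLines("data_particles", no_loop)
  expect_error(read_particle_star(no_loop, pixel_size = 1),
               class = "lamellar_format_error")

  missing_col <- withr::local_tempfile(fileext = ".star")
  writeLines(c(
    "data_particles", "", "loop_",
    "_rlnCoordinateX #1", "_rlnCoordinateY #2", "_rlnCoordinateZ #3",
    "1 2 3"
  ), missing_col)
  expect_error(read_particle_star(missing_col, pixel_size = 1),
               class = "lamellar_format_error")
})

test_that("particle table validation rejects duplicates and bad values", {
  good <- toy_particles(c(1, 2, 3))
  expect_silent(validate_particle_table(good))
  dup <- good
  dup$particle_id[2] <- dup$particle_id[1]
  expect_error(validate_particle_table(dup), class = "lamellar_validation_error")
  inf <- good
  inf$x[1] <- Inf
  expect_error(validate_particle_table(inf), class = "lamellar_validation_error")
  neg <- good
  neg$depth_nm[1] <- -1
  expect_error(validate_particle_table(neg), class = "lamellar_validation_error")
  expect_error(validate_particle_table(good[, c("particle_id", "x")]),
               class = "lamellar_format_error")
})

test_that("boundary models round-trip through the point-list format", {
  pts <- tibble::tibble(
    surface = rep(c("top", "bottom"), each = 6),
    x = rep(c(0, 500, 1000), 4),
    y = rep(rep(c(0, 400), each = 3), 2),
    z = c(100, 110, 120, 105, 115, 125, -100, -90, -80, -95, -85, -75)
  )
  model <- boundary_model(pts, tomogram_id = "rt", axis = "y")
  path <- withr::local_tempfile(fileext = ".txt")
  write_boundary_points(model, path)
  back <- read_boundary_points(path, tomogram_id = "rt", axis = "y")
  expect_equal(back$points$z, model$points$z, tolerance = 1e-9)
  expect_equal(back$points$u, model$points$u, tolerance = 1e-9)
  expect_equal(back$points$surface, model$points$surface)
  expect_equal(back$axis, "y")
})

test_that("pixel-unit boundary files are converted and require a pixel size", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# units: px",
    "1 1 0 0 100", "1 1 500 0 100",
    "1 2 0 400 100", "1 2 500 400 100",
    "2 1 0 0 -100", "2 1 500 0 -100",
    "2 2 0 400 -100", "2 2 500 400 -100"
  ), path)
  expect_error(read_boundary_points(path), class = "lamellar_format_error")
  model <- read_boundary_points(path, pixel_size = 19)
  # nm = px * 19 / 10
  expect_equal(range(model$points$z), c(-190, 190))
})

test_that("top and bottom are identified by mean z, not by object id order", {
  path <- withr::local_tempfile(fileext = ".txt")
  # object 1 is the LOWER sheet here
  writeLines(c(
    "1 1 0 0 -100", "1 1 500 0 -100",
    "1 2 0 400 -100", "1 2 500 400 -100",
    "2 1 0 0 100", "2 1 500 0 100",
    "2 2 0 400 100", "2 2 500 400 100"
  ), path)
  model <- read_boundary_points(path)
  top_z <- model$points$z[model$points$surface == "top"]
  bottom_z <- model$points$z[model$points$surface == "bottom"]
  expect_true(all(top_z > bottom_z))
})

test_that("boundary model validation rejects degenerate inputs", {
  one_plane <- tibble::tibble(
    surface = c("top", "top", "bottom", "bottom"),
    x = c(0, 500, 0, 500), y = 0, z = c(100, 100, -100, -100)
  )
  expect_error(boundary_model(one_plane), class = "lamellar_validation_error")

  single_point <- tibble::tibble(
    surface = c("top", "top", "bottom", "top", "top", "bottom", "bottom"),
    x = c(0, 500, 0, 0, 500, 0, 500),
    y = c(0, 0, 0, 400, 400, 400, 400),
    z = c(100, 100, -100, 100, 100, -100, -100)
  )
  expect_error(boundary_model(single_point), class = "lamellar_validation_error")

  crossing <- tibble::tibble(
    surface = rep(c("top", "bottom"), each = 4),
    x = rep(c(0, 500), 4),
    y = rep(rep(c(0, 400), each = 2), 2),
    z = c(100, -150, 100, 100, -100, 140, -100, -100)
  )
  expect_error(boundary_model(crossing), class = "lamellar_validation_error")
})

test_that("contour points within the plane tolerance cluster into one plane", {
  # y = 0 and y = 3 nm belong to one hand-drawn contour; y = 400 is another
  pts <- tibble::tibble(
    surface = rep(c("top", "bottom"), each = 4),
    x = rep(c(0, 1000), 4),
    y = rep(c(0, 3, 400, 400), 2),
    z = c(100, 100, 110, 110, -100, -100, -90, -90)
  )
  model <- boundary_model(pts, axis = "y")
  expect_equal(length(unique(model$points$plane)), 2L)
})

test_that("MRC volumes round-trip with header-derived voxel size", {
  set.seed(11)
  # float32-representable values so the round trip is bit-exact
  data <- array(round(rnorm(16^3, 0, 100)) / 4, dim = c(16, 16, 16))
  vol <- voxel_volume(data, 1.9)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(vol, path)
  back <- read_mrc(path)
  expect_identical(dim(back$data), dim(vol$data))
  expect_equal(max(abs(back$data - vol$data)), 0)
  expect_equal(back$voxel_size, 1.9, tolerance = 1e-6)
  expect_equal(file.size(path), 1024 + 4 * 16^3)
})

test_that("the MRC reader rejects unsupported modes and truncated files", {
  path <- withr::local_tempfile(fileext = ".mrc")
  vol <- voxel_volume(array(0, dim = c(4, 4, 4)), 1)
  write_mrc(vol, path)
  raw <- readBin(path, "raw", n = file.size(path))
  raw[13:16] <- as.raw(c(1, 0, 0, 0)) # MODE = 1 (int16)
  writeBin(raw, path)
  expect_error(read_mrc(path), class = "lamellar_format_error")

  write_mrc(vol, path)
  truncated <- readBin(path, "raw", n = file.size(path) - 40)
  writeBin(truncated, path)
  expect_error(read_mrc(path), class = "lamellar_format_error")
})

test_that("voxel_volume validates its arguments", {
  expect_error(voxel_volume(1:10, 1), class = "lamellar_format_error")
  expect_error(voxel_volume(matrix(0, 2, 2), 1), class = "lamellar_format_error")
  expect_error(voxel_volume(array(0, dim = c(2, 2, 2)), -1),
               class = "lamellar_domain_error")
})
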