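## Synthetic study generators with recorded ground truth.
##
## Every generator is deterministic under its seed and returns the analytic
## truth alongside the data so recovery can be tested: lamella slabs with a
## global tilt and a front-to-back thickness gradient, uniformly placed
## particles, a blobby reference "macromolecule", depth-dependent
## structure-factor attenuation (the damage model), noisy SEM milling
## measurements with a known true sputter rate, and resolution-vs-N series
## with a known B-factor.

#' Depth-dependent damage model
#'
#' Effective B-factor as a function of depth below the nearest milling
#' surface: a bulk B plus a surface excess that decays linearly to zero at
#' `damage_depth`, i.e.
#' `B(d) = b_bulk + b_surface_excess * max(0, 1 - d / damage_depth)`.
#' The linear ramp is a modelling choice; the established empirical fact it
#' encodes is only that surface damage extends some tens of nm (~30-45 nm
#' for argon) and decays with depth.
#'
#' @param b_bulk Bulk B-factor in Angstrom^2.
#' @param b_surface_excess Additional B at the surface in Angstrom^2.
#' @param damage_depth Depth at which the excess reaches zero, nm.
#' @return Object of class `damage_model`.
#' @export
damage_model <- function(b_bulk = 450, b_surface_excess = 2000, damage_depth = 40) {
  assert_nonneg(b_bulk, "b_bulk")
  assert_nonneg(b_surface_excess, "b_surface_excess")
  assert_positive(damage_depth, "damage_depth")
  structure(list(b_bulk = b_bulk, b_surface_excess = b_surface_excess,
                 damage_depth = damage_depth),
            class = "damage_model")
}

#' @rdname damage_model
#' @param dm A `damage_model`.
#' @param depth_nm Depth(s) in nm.
#' @return Effective B-factor(s) in Angstrom^2.
#' @export
effective_bfactor <- function(dm, depth_nm) {
  assert_nonneg(depth_nm, "depth_nm")
  dm$b_bulk + dm$b_surface_excess * pmax(0, 1 - depth_nm / dm$damage_depth)
}

#' Generate a synthetic lamella geometry
#'
#' A slab with a linear front-to-back thickness gradient and a global tilt
#' about the x axis, digitised into sparse contour planes the way a manual
#' boundary model is drawn (a handful of points per contour, optional z
#' jitter). The axial gap between the sheets is inflated by the tilt so the
#' slab's *normal* thickness equals the requested values.
#'
#' @param thickness_front,thickness_back Normal thickness in nm at the front
#'   (y = 0) and back (y = extent) of the lamella.
#' @param tilt Global tilt in degrees (slope of the mid-plane along y).
#' @param extent Footprint edge lengths `c(x, y)` in nm.
#' @param plane_spacing Contour plane spacing along y in nm.
#' @param points_per_contour Digitised points per contour per surface.
#' @param jitter_sd Gaussian z jitter of digitised points in nm (0 = exact).
#' @param tomogram_id Identifier attached to the model.
#' @param seed RNG seed for the jitter.
#' @return List with `model` (a [boundary_model()]) and `truth`: analytic
#'   `top`/`bottom` height functions of (x, y), `thickness(y)`, and the
#'   generating parameters.
#' @export
make_lamella_geometry <- function(thickness_front = 200, thickness_back = 350,
                                  tilt = 8, extent = c(2000, 2000),
                                  plane_spacing = 250, points_per_contour = 9,
                                  jitter_sd = 0, tomogram_id = "synth_tomo",
                                  seed = 1) {
  assert_positive(thickness_front, "thickness_front")
  assert_positive(thickness_back, "thickness_back")
  assert_positive(plane_spacing, "plane_spacing")
  if (length(extent) != 2L || any(!is.finite(extent)) || any(extent <= 0)) {
    abort("`extent` must be two positive lengths (x, y) in nm.",
          class = "lamellar_domain_error")
  }
  m <- tan(deg2rad(tilt))
  sf <- sqrt(1 + m^2)
  thickness <- function(y) {
    thickness_front + (thickness_back - thickness_front) * y / extent[2]
  }
  mid <- function(y) m * (y - extent[2] / 2)
  top_fun <- function(x, y) mid(y) + thickness(y) * sf / 2
  bottom_fun <- function(x, y) mid(y) - thickness(y) * sf / 2
  ys <- seq(0, extent[2], by = plane_spacing)
  if (tail(ys, 1) < extent[2]) ys <- c(ys, extent[2])
  xs <- seq(0, extent[1], length.out = points_per_contour)
  grid <- expand.grid(x = xs, y = ys)
  pts <- with_seed(seed, {
    jit <- function(n) if (jitter_sd > 0) rnorm(n, 0, jitter_sd) else numeric(n)
    dplyr::bind_rows(
      tibble(surface = "top", x = grid$x, y = grid$y,
             z = top_fun(grid$x, grid$y) + jit(nrow(grid))),
      tibble(surface = "bottom", x = grid$x, y = grid$y,
             z = bottom_fun(grid$x, grid$y) + jit(nrow(grid)))
    )
  })
  model <- boundary_model(pts, tomogram_id = tomogram_id, axis = "y")
  list(
    model = model,
    truth = list(
      top = top_fun, bottom = bottom_fun, thickness = thickness,
      tilt = tilt, extent = extent,
      thickness_front = thickness_front, thickness_back = thickness_back,
      jitter_sd = jitter_sd, seed = seed
    )
  )
}

## Euclidean distance from (x, y, z) to an analytic height field, using the
## local-gradient plane approximation (exact for planar sheets)
analytic_sheet_distance <- function(f, x, y, z, h = 1) {
  f0 <- f(x, y)
  gx <- (f(x + h, y) - f(x - h, y)) / (2 * h)
  gy <- (f(x, y + h) - f(x, y - h)) / (2 * h)
  abs(f0 - z) / sqrt(1 + gx^2 + gy^2)
}

#' Sample particles uniformly inside a synthetic lamella
#'
#' Uniform in the slab interior, keeping at least `margin` nm of true depth
#' to either surface. The analytic true depth of every particle is recorded.
#'
#' @param geometry Output of [make_lamella_geometry()].
#' @param n Number of particles.
#' @param margin Minimum true depth in nm.
#' @param seed RNG seed.
#' @return List with `particles` (a particle table) and `truth` (tibble of
#'   `particle_id`, `true_depth_nm`).
#' @export
sample_particles <- function(geometry, n, margin = 2, seed = 1) {
  assert_nonneg(n, "n")
  assert_nonneg(margin, "margin")
  tr <- geometry$truth
  min_half <- min(tr$thickness(c(0, tr$extent[2]))) / 2
  if (margin >= min_half) {
    abort("`margin` must be smaller than half the minimum thickness.",
          class = "lamellar_domain_error")
  }
  id <- geometry$model$tomogram_id
  if (n == 0) {
    empty <- tibble(particle_id = character(), tomogram_id = character(),
                    x = numeric(), y = numeric(), z = numeric())
    return(list(particles = empty,
                truth = tibble(particle_id = character(), true_depth_nm = numeric())))
  }
  sf <- sqrt(1 + tan(deg2rad(tr$tilt))^2)
  pts <- with_seed(seed, {
    x <- runif(n, 0, tr$extent[1])
    y <- runif(n, 0, tr$extent[2])
    lo <- tr$bottom(x, y) + margin * sf
    hi <- tr$top(x, y) - margin * sf
    z <- runif(n, lo, hi)
    tibble(x = x, y = y, z = z)
  })
  d_top <- analytic_sheet_distance(tr$top, pts$x, pts$y, pts$z)
  d_bot <- analytic_sheet_distance(tr$bottom, pts$x, pts$y, pts$z)
  particles <- tibble(
    particle_id = sprintf("%s_p%05d", id, seq_len(n)),
    tomogram_id = id,
    x = pts$x, y = pts$y, z = pts$z
  )
  list(particles = validate_particle_table(particles),
       truth = tibble(particle_id = particles$particle_id,
                      true_depth_nm = pmin(d_top, d_bot)))
}

#' Generate a blobby reference volume
#'
#' Sum of random Gaussian blobs inside a soft spherical envelope — a
#' ribosome-sized phantom with a smooth, decaying power spectrum.
#'
#' @param box Cubic box edge in voxels (>= 32).
#' @param voxel Voxel size in Angstrom.
#' @param n_blobs Number of Gaussian blobs.
#' @param seed RNG seed.
#' @return A [voxel_volume()].
#' @export
make_reference_volume <- function(box = 48, voxel = 1.9, n_blobs = 60, seed = 1) {
  if (box < 32) abort("`box` must be >= 32 voxels.", class = "lamellar_domain_error")
  assert_positive(voxel, "voxel")
  centre <- box / 2 + 0.5
  r_env <- 0.38 * box
  ax <- seq_len(box) - centre
  blobs <- with_seed(seed, {
    ## blob centres uniform in a sphere of radius 0.7 * r_env
    u <- matrix(rnorm(3 * n_blobs), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- 0.7 * r_env * runif(n_blobs)^(1 / 3)
    tibble(
      cx = centre + u[, 1] * rad,
      cy = centre + u[, 2] * rad,
      cz = centre + u[, 3] * rad,
      sd = runif(n_blobs, 1.5, 3.5),
      amp = runif(n_blobs, 0.5, 1)
    )
  })
  data <- array(0, dim = c(box, box, box))
  idx <- seq_len(box)
  for (i in seq_len(n_blobs)) {
    gx <- exp(-(idx - blobs$cx[i])^2 / (2 * blobs$sd[i]^2))
    gy <- exp(-(idx - blobs$cy[i])^2 / (2 * blobs$sd[i]^2))
    gz <- exp(-(idx - blobs$cz[i])^2 / (2 * blobs$sd[i]^2))
    data <- data + blobs$amp[i] * (gx %o% gy %o% gz)
  }
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  env <- array(0, dim = dim(r))
  env[r <= r_env] <- 1
  taper <- r > r_env & r <= r_env + 3
  env[taper] <- 0.5 * (1 + cos(pi * (r[taper] - r_env) / 3))
  voxel_volume(data * env, voxel)
}

#' Simulate damaged, noisy sub-volumes
#'
#' Each particle's sub-volume is the reference attenuated by
#' `exp(-B(d) s^2 / 4)` — with B(d) from the damage model at the particle's
#' depth — plus white Gaussian noise. No CTF or missing wedge is simulated.
#'
#' @param ref Reference [voxel_volume()].
#' @param particles Particle table with a `depth_nm` column (true or
#'   annotated depth).
#' @param damage A [damage_model()].
#' @param noise_sd White-noise standard deviation per voxel.
#' @param seed RNG seed.
#' @return List with `volumes` (list of `voxel_volume`) and `truth`
#'   (tibble of `particle_id`, `depth_nm`, `bfactor`).
#' @export
simulate_subvolumes <- function(ref, particles, damage, noise_sd = 1, seed = 1) {
  stopifnot(inherits(ref, "voxel_volume"), inherits(damage, "damage_model"))
  particles <- validate_particle_table(particles)
  if (!"depth_nm" %in% names(particles) || anyNA(particles$depth_nm)) {
    abort("particles must carry depth_nm.", class = "lamellar_validation_error")
  }
  assert_cubic(ref)
  n <- dim(ref$data)[1]
  s2 <- fft_s2_grid(n, ref$voxel_size)
  fref <- fft(ref$data)
  b <- effective_bfactor(damage, particles$depth_nm)
  nv <- length(ref$data)
  volumes <- with_seed(seed, {
    lapply(seq_len(nrow(particles)), function(i) {
      filt <- exp(-b[i] * s2 / 4)
      dat <- Re(fft(fref * filt, inverse = TRUE)) / nv
      if (noise_sd > 0) dat <- dat + rnorm(nv, 0, noise_sd)
      voxel_volume(dat, ref$voxel_size)
    })
  })
  list(volumes = volumes,
       truth = tibble(particle_id = particles$particle_id,
                      depth_nm = particles$depth_nm, bfactor = b))
}

#' Simulate the two half-maps of a damaged particle set directly
#'
#' Statistically identical to averaging [simulate_subvolumes()] output over
#' a random half split, but computed in closed form: each half-map is the
#' reference filtered by the mean attenuation of its particles plus white
#' noise of standard deviation `noise_sd / sqrt(n_half)`. This keeps large
#' synthetic studies cheap without changing the sampling distribution.
#'
#' @inheritParams simulate_subvolumes
#' @param split_seed Seed for the random half split.
#' @return List of two `voxel_volume` half-maps.
#' @export
simulate_damaged_half_maps <- function(ref, particles, damage, noise_sd = 1,
                                       seed = 1, split_seed = 1) {
  stopifnot(inherits(ref, "voxel_volume"), inherits(damage, "damage_model"))
  particles <- validate_particle_table(particles)
  assert_cubic(ref)
  n_part <- nrow(particles)
  if (n_part < 2L) abort("need at least 2 particles.", class = "lamellar_domain_error")
  b <- effective_bfactor(damage, particles$depth_nm)
  n <- dim(ref$data)[1]
  s2vec <- as.vector(fft_s2_grid(n, ref$voxel_size)) / 4
  fref <- fft(ref$data)
  nv <- length(ref$data)
  perm <- with_seed(split_seed, sample.int(n_part))
  halves <- list(perm[seq_len(ceiling(n_part / 2))],
                 perm[-seq_len(ceiling(n_part / 2))])
  with_seed(seed, {
    lapply(halves, function(idx) {
      filt <- numeric(nv)
      for (i in idx) filt <- filt + exp(-b[i] * s2vec)
      filt <- array(filt / length(idx), dim = dim(ref$data))
      dat <- Re(fft(fref * filt, inverse = TRUE)) / nv
      if (noise_sd > 0) dat <- dat + rnorm(nv, 0, noise_sd / sqrt(length(idx)))
      voxel_volume(dat, ref$voxel_size)
    })
  }) |> setNames(c("half1", "half2"))
}

#' Simulate SEM milling-rate measurements with a known true rate
#'
#' Inverts the parallelepiped volume relation to produce SEM distances
#' consistent with the charge-dosed volume, then perturbs the measured
#' depth-direction distance z_m with additive Gaussian noise of standard
#' deviation `noise_frac` times the series-mean true z_m. The
#' depth-direction edge is the hard SEM measurement; the in-plane distance
#' of the patterned square is taken as exact. A constant absolute depth
#' error keeps the rate-vs-current noise homoscedastic, the regime in which
#' the through-origin fit's standard error is correctly specified.
#'
#' @param true_rate True milling rate in um^3/nC.
#' @param currents Beam currents in nA, one per measurement.
#' @param times Milling times in s (recycled).
#' @param noise_frac Depth measurement noise as a fraction of the
#'   series-mean true depth distance.
#' @param alpha,theta Milling and SEM-FIB angles in degrees.
#' @param w Pattern width in um.
#' @param seed RNG seed.
#' @return List with `measurements` (a `milling_measurement` tibble) and
#'   `truth` (`true_rate`, per-row true volumes).
#' @export
simulate_milling_measurements <- function(true_rate,
                                          currents = rep(c(0.5, 0.75, 1, 1.25, 1.5, 2), each = 3),
                                          times = 60, noise_frac = 0.05,
                                          alpha = 90, theta = 52, w = 5, seed = 1) {
  assert_positive(true_rate, "true_rate")
  assert_positive(currents, "currents")
  assert_positive(times, "times")
  assert_nonneg(noise_frac, "noise_frac")
  times <- rep_len(times, length(currents))
  v_true <- true_rate * currents * times  # um^3 (nA * s = nC)
  a <- deg2rad(alpha); t <- deg2rad(theta)
  geom <- sin(a) / (sin(a + t) * sin(t))
  b_true <- rep(w, length(currents))
  z_true <- v_true / (w * b_true * geom)
  meas <- with_seed(seed, {
    zm <- z_true + rnorm(length(currents), 0, noise_frac * mean(z_true))
    milling_measurement(w = w, b_m = b_true, z_m = zm, alpha = alpha,
                        theta = theta, mill_time = times, current = currents)
  })
  list(measurements = meas,
       truth = list(true_rate = true_rate, volume_um3 = v_true))
}

#' Simulate a resolution-vs-particle-number series
#'
#' Points on the Rosenthal-Henderson line `1/d^2 = (2/B) ln(n) + intercept`,
#' optionally perturbed by relative noise on the resolution d or additive
#' noise on `1/d^2`.
#'
#' @param bfactor True B-factor in Angstrom^2.
#' @param n_values Particle counts.
#' @param intercept Intercept of `1/d^2` vs `ln(n)`; the default anchors the
#'   worst resolution (smallest n) at 20 Angstrom.
#' @param rel_noise_d Fractional Gaussian noise applied to d.
#' @param noise_sd Additive Gaussian noise applied to `1/d^2`.
#' @param seed RNG seed.
#' @return Tibble with `n` and `d` (Angstrom).
#' @export
simulate_resolution_curve <- function(bfactor,
                                      n_values = round(100 * 2^(0:9)),
                                      intercept = NULL,
                                      rel_noise_d = 0, noise_sd = 0, seed = 1) {
  assert_positive(bfactor, "bfactor")
  if (any(n_values <= 1)) abort("`n_values` must be > 1.", class = "lamellar_domain_error")
  slope <- 2 / bfactor
  if (is.null(intercept)) intercept <- 1 / 20^2 - slope * log(min(n_values))
  y <- slope * log(n_values) + intercept
  if (any(y <= 0)) {
    abort("parameters yield non-positive 1/d^2; raise the intercept.",
          class = "lamellar_domain_error")
  }
  d <- 1 / sqrt(y)
  if (rel_noise_d > 0 || noise_sd > 0) {
    d <- with_seed(seed, {
      if (noise_sd > 0) {
        y2 <- y + rnorm(length(y), 0, noise_sd)
        if (any(y2 <= 0)) abort("noise drove 1/d^2 non-positive.",
                                class = "lamellar_domain_error")
        d <- 1 / sqrt(y2)
      }
      if (rel_noise_d > 0) d <- d * (1 + rnorm(length(d), 0, rel_noise_d))
      d
    })
  }
  tibble(n = n_values, d = d)
}
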