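# Independent oracles used by the test suite. Both are deliberately naive
# implementations that share no code with the package internals.

# Volume of a tilted cross-section mill computed from first principles:
# reconstruct the cross-section parallelogram's vertices from the
# SEM-measured distances, take its area by the shoelace formula, and
# multiply by the pattern width. The side along the original surface is
# b_m / sin(alpha + theta) and the side along the beam is z_m / sin(theta)
# (both SEM distances are foreshortened projections), with the beam
# descending at alpha below the surface.
shoelace_parallelepiped_volume <- function(w, b_m, z_m, alpha_deg, theta_deg) {
  a <- alpha_deg * pi / 180
  t <- theta_deg * pi / 180
  b <- b_m / sin(a + t)
  l <- z_m / sin(t)
  px <- c(0, b, b + l * cos(a), l * cos(a))
  py <- c(0, 0, -l * sin(a), -l * sin(a))
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  area <- abs(sum(px[j] * py - px * py[j])) / 2
  w * area
}

# Brute-force distance to the nearer interpolated sheet: densely sample
# both height fields on a lateral grid around each particle and take the
# minimum 3D point distance. `window` must exceed the largest possible
# lateral offset of the true foot point; `step` bounds the discretisation
# error (<= step^2 / (8 * depth) for planar sheets).
dense_oracle_depth <- function(s, x, y, z, window = 50, step = 2, chunk = 200) {
  off <- seq(-window, window, by = step)
  g <- expand.grid(du = off, dv = off)
  m <- nrow(g)
  n <- length(x)
  if (s$axis == "y") {
    u0 <- x
    v0 <- y
  } else {
    u0 <- y
    v0 <- x
  }
  out <- numeric(n)
  for (lo in seq(1, n, by = chunk)) {
    ii <- lo:min(lo + chunk - 1, n)
    uu <- rep(u0[ii], each = m) + g$du
    vv <- rep(v0[ii], each = m) + g$dv
    pz <- rep(z[ii], each = m)
    best <- rep(Inf, length(ii))
    for (surf in c("top", "bottom")) {
      zz <- surface_height(s, surf, uu, vv, uv = TRUE)
      d2 <- g$du^2 + g$dv^2 + (zz - pz)^2
      best <- pmin(best, apply(matrix(d2, nrow = m), 2, min))
    }
    out[ii] <- sqrt(best)
  }
  out
}

# Small annotated particle table with hand-chosen depths, for shell tests.
toy_particles <- function(depths, tomogram_id = "t1") {
  tibble::tibble(
    particle_id = sprintf("%s_p%03d", tomogram_id, seq_along(depths)),
    tomogram_id = tomogram_id,
    x = 0, y = 0, z = 0,
    depth_nm = depths
  )
}
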