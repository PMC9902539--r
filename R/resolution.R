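## Half-map Fourier shell correlation, threshold resolution and
## Rosenthal-Henderson B-factor estimation.
##
## Conventions: radial shells one Fourier voxel wide (nearest-integer
## radius), shell centre frequency k / (n * voxel) in 1/Angstrom; the
## reported resolution is the first downward crossing of the threshold,
## located by linear interpolation between adjacent shells. Masks are plain
## multiplicative soft masks; no phase-randomisation correction is applied
## (the at-mask flag names the difference from refinement-suite conventions).

## integer frequency index per FFT axis position: 0, 1, ..., n/2, -(n/2-1), ..., -1
fft_axis_freq <- function(n) {
  half <- n %/% 2
  c(0:half, seq_len(n - half - 1) - (n - half))
}

## nearest-voxel radial shell index (0-based) for every FFT voxel
fft_shell_index <- function(n) {
  k <- fft_axis_freq(n)
  k2 <- k^2
  r2 <- outer(outer(k2, k2, `+`), k2, `+`)
  round(sqrt(r2))
}

#' Average a particle stack into two random half-maps
#'
#' Splits the sub-volumes into two equal halves at random (seeded) and
#' averages each voxel-wise, the standard construction feeding a half-map
#' FSC. Inputs are assumed pre-aligned.
#'
#' @param subvolumes List of [voxel_volume()]s on identical grids.
#' @param split_seed RNG seed for the split.
#' @return List of two `voxel_volume` half-maps (`half1`, `half2`).
#' @export
half_set_average <- function(subvolumes, split_seed = 1) {
  n <- length(subvolumes)
  if (n < 2L) abort("need at least 2 sub-volumes.", class = "lamellar_domain_error")
  dims <- lapply(subvolumes, function(v) dim(v$data))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    abort("sub-volume grids differ.", class = "lamellar_dimension_error")
  }
  perm <- with_seed(split_seed, sample.int(n))
  h1 <- perm[seq_len(ceiling(n / 2))]
  h2 <- perm[-seq_len(ceiling(n / 2))]
  avg <- function(idx) {
    acc <- subvolumes[[idx[1]]]$data
    for (i in idx[-1]) acc <- acc + subvolumes[[i]]$data
    voxel_volume(acc / length(idx), subvolumes[[1]]$voxel_size)
  }
  list(half1 = avg(h1), half2 = avg(h2))
}

#' Soft spherical mask
#'
#' 1 inside `radius_voxels`, cosine taper over `soft_edge_voxels`, 0 outside.
#' Centred on the FFT box centre (voxel `n %/% 2 + 1` on each axis).
#'
#' @param shape Grid edge length in voxels (cubic box).
#' @param radius_voxels Hard radius in voxels.
#' @param soft_edge_voxels Taper width in voxels.
#' @param voxel_size Voxel size in Angstrom carried on the output.
#' @return A [voxel_volume()] with values in \[0, 1\].
#' @export
spherical_mask <- function(shape, radius_voxels, soft_edge_voxels = 3,
                           voxel_size = 1) {
  assert_nonneg(radius_voxels, "radius_voxels")
  assert_nonneg(soft_edge_voxels, "soft_edge_voxels")
  if (radius_voxels + soft_edge_voxels > shape / 2) {
    abort("mask (radius + soft edge) exceeds the grid half-extent.",
          class = "lamellar_domain_error")
  }
  centre <- shape %/% 2 + 1
  ax <- (seq_len(shape) - centre)^2
  r <- sqrt(outer(outer(ax, ax, `+`), ax, `+`))
  m <- array(0, dim = c(shape, shape, shape))
  m[r <= radius_voxels] <- 1
  if (soft_edge_voxels > 0) {
    taper <- r > radius_voxels & r <= radius_voxels + soft_edge_voxels
    m[taper] <- 0.5 * (1 + cos(pi * (r[taper] - radius_voxels) / soft_edge_voxels))
  }
  voxel_volume(m, voxel_size)
}

#' Fourier shell correlation between two maps
#'
#' Per radial shell of one Fourier voxel,
#' `Re(sum(Fa * Conj(Fb))) / sqrt(sum |Fa|^2 * sum |Fb|^2)`.
#'
#' @param a,b [voxel_volume()]s on the same cubic grid with the same voxel
#'   size.
#' @param mask Optional `voxel_volume` applied multiplicatively to both maps
#'   before the transform.
#' @return Object of class `fsc_curve`: tibble-backed shells with `shell`,
#'   `freq` (1/Angstrom), `value`, `n_voxels`, plus `voxel_size` and `n`
#'   (box size). [tidy()] returns the shell table.
#' @export
fsc_curve <- function(a, b, mask = NULL) {
  stopifnot(inherits(a, "voxel_volume"), inherits(b, "voxel_volume"))
  assert_cubic(a); assert_cubic(b)
  if (!identical(dim(a$data), dim(b$data))) {
    abort("maps have different grids.", class = "lamellar_dimension_error")
  }
  if (abs(a$voxel_size - b$voxel_size) > 1e-6 * a$voxel_size) {
    abort("maps have different voxel sizes.", class = "lamellar_dimension_error")
  }
  da <- a$data; db <- b$data
  if (!is.null(mask)) {
    if (!identical(dim(mask$data), dim(da))) {
      abort("mask grid differs from the maps.", class = "lamellar_dimension_error")
    }
    da <- da * mask$data
    db <- db * mask$data
  }
  n <- dim(da)[1]
  fa <- fft(da); fb <- fft(db)
  shell <- fft_shell_index(n)
  keep <- shell <= n %/% 2
  idx <- shell[keep] + 1L
  cross <- Re(fa[keep] * Conj(fb[keep]))
  pa <- Mod(fa[keep])^2
  pb <- Mod(fb[keep])^2
  num <- as.vector(rowsum(cross, idx))
  da2 <- as.vector(rowsum(pa, idx))
  db2 <- as.vector(rowsum(pb, idx))
  nvox <- as.vector(rowsum(rep(1, sum(keep)), idx))
  denom <- sqrt(da2 * db2)
  value <- ifelse(denom > 0, num / denom, NA_real_)
  shells <- tibble(
    shell = seq_along(value) - 1L,
    freq = (seq_along(value) - 1L) / (n * a$voxel_size),
    value = value,
    n_voxels = nvox
  )
  structure(list(shells = shells, voxel_size = a$voxel_size, n = n,
                 masked = !is.null(mask)),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  res <- resolution_at_threshold(x)
  cat(sprintf("FSC curve (%d^3 box, %.3g A/voxel%s): FSC=0.143 at %.2f A%s\n",
              x$n, x$voxel_size, if (x$masked) ", masked" else "",
              res$resolution_A, if (res$at_nyquist) " (at Nyquist)" else ""))
  invisible(x)
}

#' @rdname fsc_curve
#' @param x An `fsc_curve`.
#' @param ... Unused.
#' @export
tidy.fsc_curve <- function(x, ...) x$shells

#' Resolution at an FSC threshold
#'
#' Locates the first downward crossing of the threshold by linear
#' interpolation between adjacent shells and reports 1/frequency. If the
#' curve never drops below the threshold the Nyquist resolution is returned
#' and flagged.
#'
#' @param curve An [fsc_curve()].
#' @param threshold FSC threshold, 0.143 by default (the half-map gold
#'   standard criterion).
#' @return One-row tibble with `resolution_A` and `at_nyquist`.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  sh <- curve$shells[curve$shells$shell > 0 & !is.na(curve$shells$value), ]
  if (!nrow(sh)) abort("empty FSC curve.", class = "lamellar_domain_error")
  v <- sh$value; f <- sh$freq
  below <- which(v < threshold)
  if (!length(below)) {
    return(tibble(resolution_A = nyquist_limit(curve$voxel_size), at_nyquist = TRUE))
  }
  i <- below[1]
  if (i == 1L) {
    f_cross <- f[1]
  } else {
    f_cross <- f[i - 1] + (threshold - v[i - 1]) * (f[i] - f[i - 1]) / (v[i] - v[i - 1])
  }
  tibble(resolution_A = 1 / f_cross, at_nyquist = FALSE)
}

#' Nyquist resolution limit of a sampling rate
#'
#' @param voxel_size Voxel (pixel) size in Angstrom.
#' @return Finest resolvable spacing, `2 * voxel_size`, in Angstrom.
#' @export
#' @examples
#' nyquist_limit(1.9) # 3.8 A
nyquist_limit <- function(voxel_size) {
  assert_positive(voxel_size, "voxel_size")
  2 * voxel_size
}

#' Apply B-factor attenuation to a map
#'
#' Multiplies the structure factors by `exp(-B s^2 / 4)` where `s` is the
#' spatial frequency in 1/Angstrom — the Gaussian amplitude falloff used to
#' model radiation/beam damage and alignment error.
#'
#' @param vol A cubic [voxel_volume()].
#' @param bfactor B in Angstrom^2 (>= 0).
#' @return The attenuated `voxel_volume`.
#' @export
attenuate_bfactor <- function(vol, bfactor) {
  assert_nonneg(bfactor, "bfactor")
  assert_cubic(vol)
  if (bfactor == 0) return(vol)
  n <- dim(vol$data)[1]
  s2 <- fft_s2_grid(n, vol$voxel_size)
  filt <- exp(-bfactor * s2 / 4)
  voxel_volume(Re(fft(fft(vol$data) * filt, inverse = TRUE)) / length(vol$data),
               vol$voxel_size)
}

## squared spatial frequency (1/A^2) over the FFT grid
fft_s2_grid <- function(n, voxel_size) {
  k <- fft_axis_freq(n) / (n * voxel_size)
  k2 <- k^2
  outer(outer(k2, k2, `+`), k2, `+`)
}

#' Rosenthal-Henderson B-factor from a resolution-vs-N series
#'
#' Fits `1/d^2` against `ln(n)` by ordinary least squares; the B-factor is
#' 2 over the slope (Angstrom^2). A flat or negative slope (resolution not
#' improving with particle number) is outside the validity regime and is an
#' error.
#'
#' @param points Data frame with columns `n` (particle count, > 1) and `d`
#'   (resolution in Angstrom, > 0).
#' @return Object of class `bfactor_fit`: `bfactor`, `slope`, `intercept`,
#'   `points`, `fit`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' pts <- data.frame(n = c(100, 10000), d = c(20, 10))
#' rosenthal_henderson_bfactor(pts)$bfactor
rosenthal_henderson_bfactor <- function(points) {
  points <- as_tibble(points)
  if (!all(c("n", "d") %in% names(points))) {
    abort("`points` needs columns `n` and `d`.", class = "lamellar_format_error")
  }
  if (nrow(points) < 2L) {
    abort("at least 2 (n, d) points are required.", class = "lamellar_domain_error")
  }
  if (any(points$n <= 1) || any(points$d <= 0)) {
    abort("need n > 1 and d > 0.", class = "lamellar_domain_error")
  }
  x <- log(points$n)
  y <- 1 / points$d^2
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[["x"]])
  if (slope <= 0) {
    abort("non-positive slope: resolution does not improve with particle number.",
          class = "lamellar_domain_error")
  }
  structure(
    list(bfactor = 2 / slope, slope = slope,
         intercept = unname(coef(fit)[["(Intercept)"]]),
         points = points, fit = fit),
    class = "bfactor_fit"
  )
}

#' @export
print.bfactor_fit <- function(x, ...) {
  cat(sprintf("Rosenthal-Henderson B-factor: %.0f A^2 (slope %.3g, %d points)\n",
              x$bfactor, x$slope, nrow(x$points)))
  invisible(x)
}

#' @rdname rosenthal_henderson_bfactor
#' @param x A `bfactor_fit`.
#' @param ... Unused.
#' @export
tidy.bfactor_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = summary(x$fit)$coefficients[, "Std. Error"])
}

#' @rdname rosenthal_henderson_bfactor
#' @export
glance.bfactor_fit <- function(x, ...) {
  tibble(bfactor = x$bfactor, slope = x$slope, intercept = x$intercept,
         r.squared = summary(x$fit)$r.squared, n = nrow(x$points))
}
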