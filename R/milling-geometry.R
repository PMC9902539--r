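## Sputter-volume and milling-rate calculus for FIB cross-section experiments.
##
## Geometry conventions: alpha is the milling angle between the ion beam and
## the (ramp-flattened) sample surface; theta is the fixed angle between the
## SEM and the FIB column (52 degrees on the instruments modelled here). SEM
## distances are measured in the SEM image plane without stage movement, so
## depth-direction distances are foreshortened by sin(theta).

#' Milled volume of a perpendicular (cuboid) cross-section mill
#'
#' At normal incidence the removed volume is simply the perpendicular depth
#' times the milled pattern area.
#'
#' @param depth Perpendicular milled depth in um (after tilt correction, see
#'   [tilt_corrected_depth()]).
#' @param area Milled pattern area in um^2.
#' @return Volume in um^3.
#' @seealso [parallelepiped_volume()] for tilted mills.
#' @export
#' @examples
#' perpendicular_volume(depth = 1, area = 2)
perpendicular_volume <- function(depth, area) {
  assert_positive(depth, "depth")
  assert_positive(area, "area")
  depth * area
}

#' Tilt-correct an SEM-measured depth
#'
#' The SEM images the milled trench at an angle `theta` relative to the
#' trench wall, so a depth measured in the image is foreshortened; the true
#' perpendicular depth is the measured distance divided by `sin(theta)`.
#'
#' @param z_m SEM-measured depth-direction distance in um.
#' @param theta SEM-to-FIB column angle in degrees, in (0, 90).
#' @return Perpendicular depth in um.
#' @export
#' @examples
#' tilt_corrected_depth(1, 52) # 1 / sin(52 deg)
tilt_corrected_depth <- function(z_m, theta) {
  assert_positive(z_m, "z_m")
  if (!is.numeric(theta) || any(theta <= 0) || any(theta >= 90)) {
    abort("`theta` must lie in (0, 90) degrees.", class = "lamellar_domain_error")
  }
  z_m / sin(deg2rad(theta))
}

#' Construct a milling measurement record
#'
#' One SEM-measured milled-volume experiment: a square pattern of width `w`
#' milled at angle `alpha` into a ramp-flattened surface, with in-plane and
#' depth-direction distances `b_m` and `z_m` measured from the SEM image
#' (column at angle `theta` to the FIB).
#'
#' @param w Pattern width in um.
#' @param b_m SEM-measured in-plane distance in um.
#' @param z_m SEM-measured depth-direction distance in um.
#' @param alpha Milling angle in degrees, in (0, 90].
#' @param theta SEM-FIB column angle in degrees, in (0, 90).
#' @param mill_time Milling time in s.
#' @param current Beam current in nA.
#' @return A one-row tibble of class `milling_measurement`.
#' @export
milling_measurement <- function(w, b_m, z_m, alpha, theta = 52,
                                mill_time = NA_real_, current = NA_real_) {
  assert_positive(w, "w"); assert_positive(b_m, "b_m"); assert_positive(z_m, "z_m")
  if (any(alpha <= 0) || any(alpha > 90)) {
    abort("`alpha` must lie in (0, 90] degrees.", class = "lamellar_domain_error")
  }
  if (any(theta <= 0) || any(theta >= 90)) {
    abort("`theta` must lie in (0, 90) degrees.", class = "lamellar_domain_error")
  }
  if (any(alpha + theta >= 180)) {
    abort("`alpha + theta` must be < 180 degrees.", class = "lamellar_domain_error")
  }
  out <- tibble(
    w = w, b_m = b_m, z_m = z_m, alpha = alpha, theta = theta,
    mill_time = mill_time, current = current
  )
  class(out) <- c("milling_measurement", class(out))
  out
}

#' Milled volume of a tilted (parallelepiped) cross-section mill
#'
#' When the stage is tilted to mill at angle `alpha`, the removed volume is a
#' parallelepiped with two rectangular and two parallelogram faces. Its
#' volume follows from the SEM-measured distances as
#' \deqn{V = \frac{w\, b_m\, z_m \sin\alpha}{\sin(\alpha+\theta)\,\sin\theta}.}
#'
#' @param m A `milling_measurement` (or plain data frame with columns
#'   `w, b_m, z_m, alpha, theta`).
#' @return Volume(s) in um^3, one per row.
#' @export
#' @examples
#' m <- milling_measurement(w = 1, b_m = 1, z_m = 1, alpha = 38, theta = 52)
#' parallelepiped_volume(m) # sin(38 deg) / sin(52 deg) since alpha + theta = 90
parallelepiped_volume <- function(m) {
  need <- c("w", "b_m", "z_m", "alpha", "theta")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    abort(paste0("measurement lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "lamellar_format_error")
  }
  if (any(m$alpha + m$theta >= 180)) {
    abort("`alpha + theta` must be < 180 degrees.", class = "lamellar_domain_error")
  }
  a <- deg2rad(m$alpha); t <- deg2rad(m$theta)
  m$w * m$b_m * m$z_m * sin(a) / (sin(a + t) * sin(t))
}

#' Milling rates from a measured volume
#'
#' @param volume Milled volume in um^3.
#' @param mill_time Milling time in s.
#' @param current Beam current in nA (so that nA x s = nC).
#' @return A tibble with `rate_um3_s` (volume/time) and `rate_um3_nC`
#'   (volume/charge).
#' @export
#' @examples
#' milling_rate(16.7, 1, 1)
milling_rate <- function(volume, mill_time, current) {
  assert_positive(volume, "volume")
  assert_positive(mill_time, "mill_time")
  assert_positive(current, "current")
  tibble(
    rate_um3_s = volume / mill_time,
    rate_um3_nC = volume / (mill_time * current)
  )
}

#' Least-squares rate fit through the origin
#'
#' Fits `rate = slope * current` with no intercept, the model behind a
#' per-charge milling rate: the slope is the rate in um^3/nC and its standard
#' error comes from the one-parameter least-squares fit
#' (`sqrt(RSS / ((n-1) * sum(x^2)))`).
#'
#' @param points Data frame with columns `current` (nA) and `rate` (um^3/s);
#'   replicate measurements at the same current are individual rows.
#' @return An object of class `rate_fit` with elements `slope`, `stderr`,
#'   `points`, `n`. Use [tidy()] / [glance()] to extract tibbles.
#' @export
#' @examples
#' fit_rate_through_origin(data.frame(current = c(1, 2), rate = c(4.3, 8.6)))
fit_rate_through_origin <- function(points) {
  points <- as_tibble(points)
  if (!all(c("current", "rate") %in% names(points))) {
    abort("`points` needs columns `current` and `rate`.", class = "lamellar_format_error")
  }
  if (nrow(points) < 1L) {
    abort("at least one (current, rate) point is required.", class = "lamellar_domain_error")
  }
  assert_positive(points$current, "current")
  x <- points$current
  y <- points$rate
  n <- length(x)
  if (n >= 2L) {
    fit <- lm(y ~ 0 + x)
    slope <- unname(coef(fit)[["x"]])
    stderr <- unname(sqrt(sum(fit$residuals^2) / ((n - 1) * sum(x^2))))
  } else {
    slope <- sum(x * y) / sum(x^2)
    stderr <- 0
  }
  structure(
    list(slope = slope, stderr = stderr, points = points, n = n),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Through-origin rate fit: %.4g +/- %.2g um^3/nC (n = %d)\n",
              x$slope, x$stderr, x$n))
  invisible(x)
}

#' @rdname fit_rate_through_origin
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @export
tidy.rate_fit <- function(x, ...) {
  tibble(term = "rate_um3_nC", estimate = x$slope, std.error = x$stderr)
}

#' @rdname fit_rate_through_origin
#' @export
glance.rate_fit <- function(x, ...) {
  tibble(slope = x$slope, stderr = x$stderr, n = x$n)
}

#' Ratio of two milling rates
#'
#' Fold difference between two per-charge rates, rounded (half-to-even) at a
#' stated digit count so printed folds are reproduced deterministically.
#'
#' @param rate_a,rate_b Rates in um^3/nC; `rate_b` is the denominator.
#' @param ndigits Digits to round the fold to.
#' @return The rounded fold change `rate_a / rate_b`.
#' @export
#' @examples
#' rate_ratio(16.7, 4.5, 1) # xenon vs argon at normal incidence
rate_ratio <- function(rate_a, rate_b, ndigits = 1) {
  if (any(rate_b == 0)) abort("`rate_b` must be non-zero.", class = "lamellar_domain_error")
  round_half_even(rate_a / rate_b, ndigits)
}

#' Fold change of one gas's rate across milling angles
#'
#' @param rates Named numeric vector or data frame with columns `angle` and
#'   `rate`; names/angles in degrees.
#' @param angle_from,angle_to Angles (degrees) to compare; the fold is
#'   `rate[angle_to] / rate[angle_from]`.
#' @param ndigits Digits to round to.
#' @return The rounded fold change.
#' @export
#' @examples
#' argon <- c(`90` = 4.5, `10` = 59.3)
#' fold_change_across_angles(argon, 90, 10, 0) # 13-fold from normal to glancing
fold_change_across_angles <- function(rates, angle_from, angle_to, ndigits = 1) {
  if (is.data.frame(rates)) {
    rates <- setNames(rates$rate, rates$angle)
  }
  key_from <- as.character(angle_from)
  key_to <- as.character(angle_to)
  for (k in c(key_from, key_to)) {
    if (!k %in% names(rates)) {
      abort(sprintf("no rate recorded at angle %s.", k), class = "lamellar_key_error")
    }
  }
  round_half_even(unname(rates[[key_to]] / rates[[key_from]]), ndigits)
}

#' Estimate milling time for a target volume
#'
#' Planning companion: given a per-charge rate, how long a mill of a given
#' volume takes at a given current.
#'
#' @param volume Target volume in um^3.
#' @param current Beam current in nA.
#' @param rate Milling rate in um^3/nC.
#' @return Time in s.
#' @export
estimate_milling_time <- function(volume, current, rate) {
  assert_positive(volume, "volume")
  assert_positive(current, "current")
  assert_positive(rate, "rate")
  volume / (rate * current)
}
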