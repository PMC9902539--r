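## Continuous lamella surfaces from sparse boundary models.
##
## Within a contour plane the digitised points are linearly interpolated
## along u; between planes the two plane profiles are linearly blended along
## the sparse axis. Evaluation outside the digitised range clamps to the
## nearest digitised column/plane. Distances are unsigned 3D Euclidean
## point-to-sheet distances (surfaces are tilted, so the axial z-gap would
## overestimate depth).

#' Interpolate a boundary model into continuous surfaces
#'
#' @param model A [boundary_model()].
#' @return An object of class `surface_model` with piecewise-linear top and
#'   bottom height fields over the tomogram footprint. Evaluate with
#'   [surface_height()].
#' @export
interpolate_surfaces <- function(model) {
  stopifnot(inherits(model, "boundary_model"))
  pts <- model$points
  plane_ids <- sort(unique(pts$plane))
  plane_pos <- vapply(plane_ids, function(p) pts$axis_position[pts$plane == p][1],
                      numeric(1))
  mk <- function(surface) {
    lapply(plane_ids, function(p) {
      sub <- pts[pts$plane == p & pts$surface == surface, ]
      sub <- sub[order(sub$u), ]
      list(u = sub$u, z = sub$z)
    })
  }
  s <- structure(
    list(
      tomogram_id = model$tomogram_id,
      axis = model$axis,
      plane_pos = plane_pos,
      top = mk("top"),
      bottom = mk("bottom"),
      footprint = list(u = model$extent$u, v = range(plane_pos))
    ),
    class = "surface_model"
  )
  ## reject models whose interpolated surfaces cross between the contours
  uu <- seq(s$footprint$u[1], s$footprint$u[2], length.out = 21)
  vv <- seq(s$footprint$v[1], s$footprint$v[2], length.out = 21)
  g <- expand.grid(u = uu, v = vv)
  tz <- surface_height(s, "top", g$u, g$v, uv = TRUE)
  bz <- surface_height(s, "bottom", g$u, g$v, uv = TRUE)
  if (any(tz <= bz)) {
    k <- which(tz <= bz)[1]
    abort(sprintf("interpolated surfaces cross near (u=%.1f, v=%.1f) nm.",
                  g$u[k], g$v[k]),
          class = "lamellar_validation_error")
  }
  s
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("Surface model '%s': %d planes, footprint u [%.0f, %.0f] x v [%.0f, %.0f] nm\n",
              x$tomogram_id, length(x$plane_pos),
              x$footprint$u[1], x$footprint$u[2],
              x$footprint$v[1], x$footprint$v[2]))
  invisible(x)
}

#' Evaluate a surface height field
#'
#' @param s A `surface_model`.
#' @param surface `"top"` or `"bottom"`.
#' @param x,y Query coordinates in nm (tomogram frame). With `uv = TRUE`,
#'   `x` is interpreted as the in-plane coordinate u and `y` as the sparse
#'   axis position v regardless of the model's axis.
#' @param uv Use (u, v) coordinates directly.
#' @return Heights z in nm, clamped evaluation outside the digitised range.
#' @export
surface_height <- function(s, surface = c("top", "bottom"), x, y, uv = FALSE) {
  surface <- match.arg(surface)
  if (uv || s$axis == "y") { u <- x; v <- y } else { u <- y; v <- x }
  planes <- s[[surface]]
  pos <- s$plane_pos
  np <- length(pos)
  v <- pmin(pmax(v, pos[1]), pos[np])
  j <- findInterval(v, pos, all.inside = TRUE)
  w <- (v - pos[j]) / (pos[j + 1] - pos[j])
  w <- pmin(pmax(w, 0), 1)
  z_lo <- numeric(length(u)); z_hi <- numeric(length(u))
  for (p in unique(j)) {
    sel <- which(j == p)
    z_lo[sel] <- approx(planes[[p]]$u, planes[[p]]$z, u[sel], rule = 2, ties = mean)$y
    z_hi[sel] <- approx(planes[[p + 1]]$u, planes[[p + 1]]$z, u[sel], rule = 2, ties = mean)$y
  }
  (1 - w) * z_lo + w * z_hi
}

## multi-level grid minimisation of squared point-to-sheet distance,
## vectorised over all query points: at each level a (2k+1)^2 grid of
## candidate (u, v) foot points per query shrinks around the current best
surface_distance_batch <- function(s, surface, u0, v0, pz, levels = 4, k = 6) {
  n <- length(u0)
  gap <- abs(surface_height(s, "top", u0, v0, uv = TRUE) -
             surface_height(s, "bottom", u0, v0, uv = TRUE))
  half <- pmax(40, 0.5 * gap)   # lateral search radius, nm
  side <- 2 * k + 1
  g <- expand.grid(du = seq(-1, 1, length.out = side),
                   dv = seq(-1, 1, length.out = side))
  m <- nrow(g)
  cu <- u0; cv <- v0
  best <- rep(Inf, n)
  rep_u0 <- rep(u0, each = m); rep_v0 <- rep(v0, each = m)
  rep_pz <- rep(pz, each = m)
  for (level in seq_len(levels)) {
    hh <- rep(half, each = m)
    U <- rep(cu, each = m) + g$du * hh
    V <- rep(cv, each = m) + g$dv * hh
    zz <- surface_height(s, surface, U, V, uv = TRUE)
    d2 <- (U - rep_u0)^2 + (V - rep_v0)^2 + (zz - rep_pz)^2
    d2m <- matrix(d2, nrow = m)
    kmin <- max.col(-t(d2m), ties.method = "first")
    idx <- kmin + (seq_len(n) - 1L) * m
    best <- pmin(best, d2[idx])
    cu <- U[idx]; cv <- V[idx]
    half <- half / k   # shrink to one grid cell each side
  }
  sqrt(best)
}

#' Distance from a point to the nearest milling surface
#'
#' Unsigned Euclidean distance from each query point to the closer of the
#' interpolated top and bottom sheets, found by a multi-level grid search on
#' the continuous height fields (final grid cell well below 0.1 nm). Ties
#' report the top surface.
#'
#' @param s A `surface_model`.
#' @param x,y,z Point coordinates in nm (vectors of equal length).
#' @return Tibble with `distance_nm`, `side` ("top"/"bottom") and
#'   `out_of_footprint` (TRUE when the point's (x, y) lies outside the
#'   digitised footprint and evaluation was clamped).
#' @export
distance_to_nearest_surface <- function(s, x, y, z) {
  stopifnot(inherits(s, "surface_model"))
  if (s$axis == "y") { u0 <- x; v0 <- y } else { u0 <- y; v0 <- x }
  d_top <- surface_distance_batch(s, "top", u0, v0, z)
  d_bot <- surface_distance_batch(s, "bottom", u0, v0, z)
  if (s$axis == "y") { u <- x; v <- y } else { u <- y; v <- x }
  oof <- u < s$footprint$u[1] | u > s$footprint$u[2] |
         v < s$footprint$v[1] | v > s$footprint$v[2]
  tibble(
    distance_nm = pmin(d_top, d_bot),
    side = ifelse(d_top <= d_bot, "top", "bottom"),
    out_of_footprint = oof
  )
}

#' Lamella thickness of a tomogram
#'
#' Top-to-bottom separation at the footprint centre. By default the axial
#' z-gap is projected onto the local surface normal of the mid-plane (for
#' level surfaces the two coincide); `mode = "axial"` returns the raw z-gap.
#'
#' @param s A `surface_model`.
#' @param mode `"normal"` (default) or `"axial"`.
#' @return Thickness in nm.
#' @export
tomogram_thickness <- function(s, mode = c("normal", "axial")) {
  mode <- match.arg(mode)
  uc <- mean(s$footprint$u); vc <- mean(s$footprint$v)
  gap <- surface_height(s, "top", uc, vc, uv = TRUE) -
         surface_height(s, "bottom", uc, vc, uv = TRUE)
  if (mode == "axial") return(gap)
  mid <- function(u, v) {
    (surface_height(s, "top", u, v, uv = TRUE) +
     surface_height(s, "bottom", u, v, uv = TRUE)) / 2
  }
  hu <- diff(s$footprint$u) / 200; hv <- diff(s$footprint$v) / 200
  gu <- (mid(uc + hu, vc) - mid(uc - hu, vc)) / (2 * hu)
  gv <- (mid(uc, vc + hv) - mid(uc, vc - hv)) / (2 * hv)
  gap / sqrt(1 + gu^2 + gv^2)
}

#' Annotate particles with depth and local lamella thickness
#'
#' Fills `depth_nm` (distance to the nearest milling surface) and
#' `tomo_thickness_nm` (the tomogram's centre thickness) for every particle;
#' all other columns pass through unchanged, so the operation is idempotent.
#'
#' @param t A particle table.
#' @param surfaces A single `surface_model`, or a (possibly named) list of
#'   them covering every tomogram in `t`.
#' @return The annotated particle table, with an `out_of_footprint` logical
#'   column flagging clamped evaluations.
#' @export
annotate_particles <- function(t, surfaces) {
  t <- validate_particle_table(t)
  if (inherits(surfaces, "surface_model")) surfaces <- list(surfaces)
  ids <- vapply(surfaces, function(s) s$tomogram_id, character(1))
  names(surfaces) <- ids
  unknown <- setdiff(unique(t$tomogram_id), ids)
  if (length(unknown)) {
    abort(paste0("no surface model for tomogram(s): ", paste(unknown, collapse = ", ")),
          class = "lamellar_validation_error")
  }
  t$depth_nm <- NA_real_
  t$tomo_thickness_nm <- NA_real_
  t$out_of_footprint <- NA
  for (id in unique(t$tomogram_id)) {
    sel <- which(t$tomogram_id == id)
    s <- surfaces[[id]]
    d <- distance_to_nearest_surface(s, t$x[sel], t$y[sel], t$z[sel])
    t$depth_nm[sel] <- d$distance_nm
    t$out_of_footprint[sel] <- d$out_of_footprint
    t$tomo_thickness_nm[sel] <- tomogram_thickness(s)
  }
  t
}

#' Summary statistics of a set of thickness values
#'
#' @param values Thickness values in nm.
#' @return Tibble with `mean`, `sd` (sample SD, 0 for a single value),
#'   `median`, `n`.
#' @export
thickness_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) {
    abort("no thickness values supplied.", class = "lamellar_domain_error")
  }
  tibble(
    mean = mean(values),
    sd = if (length(values) > 1) sd(values) else 0,
    median = median(values),
    n = length(values)
  )
}

#' Particle-weighted average lamella thickness
#'
#' Each particle contributes its tomogram's thickness, so tomograms with
#' more particles weigh more — the convention used when reporting the
#' thickness context of a sub-volume average.
#'
#' @param t An annotated particle table (`tomo_thickness_nm` present).
#' @return Tibble as in [thickness_summary()].
#' @export
weighted_average_thickness <- function(t) {
  t <- validate_particle_table(t)
  if (!"tomo_thickness_nm" %in% names(t) || anyNA(t$tomo_thickness_nm)) {
    abort("particles must carry tomo_thickness_nm annotations.",
          class = "lamellar_validation_error")
  }
  thickness_summary(t$tomo_thickness_nm)
}

#' Linear trend of lamella thickness against distance to the lamella edge
#'
#' Ordinary least squares with intercept, plus the pointwise 95% confidence
#' band of the fitted line.
#'
#' @param points Data frame with columns `edge_distance` (um) and
#'   `thickness` (nm).
#' @param level Confidence level for the band.
#' @return Object of class `edge_trend`: `slope`, `intercept`, `fit` (the
#'   `lm`), and `band`, a tibble of fitted values with `lwr`/`upr` over the
#'   observed range. Has [tidy()]/[glance()]/[autoplot()] methods.
#' @export
thickness_vs_edge_regression <- function(points, level = 0.95) {
  points <- as_tibble(points)
  if (!all(c("edge_distance", "thickness") %in% names(points))) {
    abort("`points` needs columns edge_distance and thickness.",
          class = "lamellar_format_error")
  }
  if (nrow(points) < 3L) {
    abort("at least 3 points are required.", class = "lamellar_domain_error")
  }
  if (diff(range(points$edge_distance)) == 0) {
    abort("edge distances are all equal; trend undefined.",
          class = "lamellar_domain_error")
  }
  fit <- lm(thickness ~ edge_distance, data = points)
  grid <- tibble(edge_distance = seq(min(points$edge_distance),
                                     max(points$edge_distance),
                                     length.out = 50))
  pr <- stats::predict(fit, newdata = grid, interval = "confidence", level = level)
  band <- dplyr::bind_cols(grid, as_tibble(as.data.frame(pr)))
  structure(
    list(slope = unname(coef(fit)[["edge_distance"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         fit = fit, band = band, data = points, level = level),
    class = "edge_trend"
  )
}

#' @export
print.edge_trend <- function(x, ...) {
  cat(sprintf("Thickness-vs-edge trend: slope %.3g nm/um, intercept %.4g nm\n",
              x$slope, x$intercept))
  invisible(x)
}

#' @rdname thickness_vs_edge_regression
#' @param x An `edge_trend`.
#' @param ... Unused.
#' @export
tidy.edge_trend <- function(x, ...) {
  as_tibble(cbind(term = c("(Intercept)", "edge_distance"),
                  as.data.frame(summary(x$fit)$coefficients)))
}

#' @rdname thickness_vs_edge_regression
#' @export
glance.edge_trend <- function(x, ...) {
  s <- summary(x$fit)
  tibble(slope = x$slope, intercept = x$intercept,
         r.squared = s$r.squared, sigma = s$sigma, n = nrow(x$data))
}
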