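## Plain-text boundary-point models.
##
## A boundary model is the manual digitisation of the two milled surfaces of
## one lamella as seen in its tomogram: sparse contours drawn every ~100
## slices, each contour a handful of points along one surface. On disk the
## model is the point-list export style, one point per line:
##
##   object_id  contour_id  x  y  z
##
## with exactly two object ids (the top and the bottom surface). Units are
## nm unless a "# units: px" header line is present, in which case a pixel
## size must be supplied to convert. Which object is "top" is decided by the
## mean z of its points, so the file's object numbering does not matter.

PLANE_TOL_NM <- 5  # hand-digitised contours are not exactly coplanar

#' Build a boundary model from digitised surface points
#'
#' Groups points into contour planes along the sparse axis (positions within
#' 5 nm are clustered into one plane), orders the planes, and validates the
#' model: at least two planes, at least two points per surface per plane, and
#' the top surface strictly above the bottom wherever both are defined.
#'
#' @param points Tibble with columns `surface` ("top"/"bottom"), `x`, `y`,
#'   `z` in nm.
#' @param tomogram_id Identifier of the tomogram the model belongs to.
#' @param axis Sparse contour axis, `"y"` (default: contours drawn in planes
#'   of constant y) or `"x"`.
#' @return An object of class `boundary_model`: a list with `tomogram_id`,
#'   `axis`, `points` (tibble with `surface`, `plane`, `axis_position`, `u`,
#'   `z`) and `extent`.
#' @export
boundary_model <- function(points, tomogram_id = "tomo", axis = c("y", "x")) {
  axis <- match.arg(axis)
  points <- as_tibble(points)
  need <- c("surface", "x", "y", "z")
  if (!all(need %in% names(points))) {
    abort("boundary points need columns surface, x, y, z.",
          class = "lamellar_format_error")
  }
  if (!all(points$surface %in% c("top", "bottom"))) {
    abort("surface must be 'top' or 'bottom'.", class = "lamellar_format_error")
  }
  v <- if (axis == "y") points$y else points$x
  u <- if (axis == "y") points$x else points$y
  ## greedy 1-d clustering of axis positions within tolerance
  ord <- order(v)
  plane_id <- integer(length(v))
  current <- 0L; anchor <- -Inf
  for (k in ord) {
    if (v[k] - anchor > PLANE_TOL_NM) {
      current <- current + 1L
      anchor <- v[k]
    }
    plane_id[k] <- current
  }
  pts <- tibble(surface = points$surface, plane = plane_id, u = u, z = points$z)
  pos <- vapply(split(v, plane_id), mean, numeric(1))
  pts$axis_position <- pos[as.character(pts$plane)]
  pts <- dplyr::arrange(pts, .data$plane, .data$surface, .data$u)
  model <- structure(
    list(
      tomogram_id = tomogram_id,
      axis = axis,
      points = pts,
      extent = list(u = range(u), axis = range(pts$axis_position))
    ),
    class = "boundary_model"
  )
  validate_boundary_model(model)
}

validate_boundary_model <- function(model) {
  pts <- model$points
  planes <- sort(unique(pts$plane))
  if (length(planes) < 2L) {
    abort("a boundary model needs at least 2 contour planes.",
          class = "lamellar_validation_error")
  }
  for (p in planes) {
    for (s in c("top", "bottom")) {
      n <- sum(pts$plane == p & pts$surface == s)
      if (n < 2L) {
        abort(sprintf("plane %d has %d '%s' point(s); at least 2 required.", p, n, s),
              class = "lamellar_validation_error")
      }
    }
    top <- pts[pts$plane == p & pts$surface == "top", ]
    bot <- pts[pts$plane == p & pts$surface == "bottom", ]
    lo <- max(min(top$u), min(bot$u)); hi <- min(max(top$u), max(bot$u))
    if (lo < hi) {
      uu <- seq(lo, hi, length.out = 25)
      tz <- approx(top$u, top$z, uu, rule = 2, ties = mean)$y
      bz <- approx(bot$u, bot$z, uu, rule = 2, ties = mean)$y
      if (any(tz <= bz)) {
        abort(sprintf("plane %d: top surface not strictly above bottom over the overlap.", p),
              class = "lamellar_validation_error")
      }
    }
  }
  model
}

#' @export
print.boundary_model <- function(x, ...) {
  cat(sprintf("Boundary model '%s': %d planes along %s, %d points\n",
              x$tomogram_id, length(unique(x$points$plane)), x$axis,
              nrow(x$points)))
  invisible(x)
}

#' Read a plain-text boundary-point model
#'
#' @param path Path to a whitespace-separated point list (`object contour x
#'   y z` per line; `#` starts a comment). A `# units: px` header switches
#'   the file to pixel units, converted with `pixel_size`.
#' @param tomogram_id Tomogram id to attach; defaults to the file name.
#' @param pixel_size Pixel size in Angstrom per pixel; only needed for
#'   pixel-unit files.
#' @param axis Sparse contour axis, see [boundary_model()].
#' @return A `boundary_model`.
#' @export
read_boundary_points <- function(path, tomogram_id = NULL, pixel_size = NULL,
                                 axis = c("y", "x")) {
  axis <- match.arg(axis)
  tomogram_id <- tomogram_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  units <- "nm"
  hdr <- grep("^#\\s*units\\s*:?", lines, value = TRUE)
  if (length(hdr) && grepl("px", hdr[[1]])) units <- "px"
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    abort(sprintf("%s: no boundary points found.", path), class = "lamellar_format_error")
  }
  fields <- strsplit(lines, "\\s+")
  bad <- which(lengths(fields) != 5L)
  if (length(bad)) {
    abort(sprintf("%s: line %d does not have 5 fields (object contour x y z).",
                  path, bad[1]),
          class = "lamellar_parse_error")
  }
  mat <- do.call(rbind, fields)
  obj <- mat[, 1]
  xyz <- apply(mat[, 3:5, drop = FALSE], 2, function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) {
      abort(sprintf("%s: non-numeric coordinate at line %d.", path, which(is.na(v))[1]),
            class = "lamellar_parse_error")
    }
    v
  })
  if (units == "px") {
    if (is.null(pixel_size)) {
      abort(sprintf("%s declares pixel units; supply `pixel_size`.", path),
            class = "lamellar_format_error")
    }
    xyz <- xyz * pixel_size / 10
  }
  ids <- unique(obj)
  if (length(ids) != 2L) {
    abort(sprintf("%s: expected exactly 2 object ids (top/bottom), found %d.",
                  path, length(ids)),
          class = "lamellar_format_error")
  }
  mean_z <- vapply(ids, function(i) mean(xyz[obj == i, 3]), numeric(1))
  top_id <- ids[which.max(mean_z)]
  pts <- tibble(
    surface = ifelse(obj == top_id, "top", "bottom"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  boundary_model(pts, tomogram_id = tomogram_id, axis = axis)
}

#' Write a boundary model as a plain-text point list
#'
#' Object 1 is the top surface, object 2 the bottom; contour ids are the
#' plane indices. Values are written in nm.
#'
#' @param model A `boundary_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundary_points <- function(model, path) {
  pts <- model$points
  obj <- ifelse(pts$surface == "top", 1L, 2L)
  if (model$axis == "y") {
    x <- pts$u; y <- pts$axis_position
  } else {
    x <- pts$axis_position; y <- pts$u
  }
  lines <- sprintf("%d %d %.15g %.15g %.15g", obj, pts$plane, x, y, pts$z)
  writeLines(c("# units: nm", lines), path)
  invisible(path)
}
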