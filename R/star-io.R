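## RELION-dialect STAR I/O for particle tables.
##
## Dialect: a single data_ block containing one loop_; coordinates in the
## rlnCoordinateX/Y/Z columns are in pixels, tomogram identity comes from
## rlnMicrographName, particle identity from rlnImageName. Depth and local
## lamella thickness annotations are written as the custom columns
## lamellarDepthNm / lamellarThicknessNm (values in nm). Unknown columns are
## carried through untouched so tables survive a read/write round trip.

DEPTH_TAG <- "lamellarDepthNm"
THICKNESS_TAG <- "lamellarThicknessNm"

## minimal STAR loop parser: returns a character data.frame plus column tags
parse_star_loop <- function(lines, path) {
  lines <- sub("#.*$", "", lines, perl = FALSE)
  lines_trim <- trimws(lines)
  loop_at <- which(lines_trim == "loop_")
  if (!length(loop_at)) {
    abort(sprintf("%s: no loop_ block found.", path), class = "lamellar_format_error")
  }
  i <- loop_at[[1]] + 1L
  tags <- character()
  while (i <= length(lines_trim) && startsWith(lines_trim[i], "_")) {
    tag <- sub("^_(\\S+).*$", "\\1", lines_trim[i])
    tags <- c(tags, tag)
    i <- i + 1L
  }
  if (!length(tags)) {
    abort(sprintf("%s: loop_ block has no column labels.", path),
          class = "lamellar_format_error")
  }
  rows <- list()
  while (i <= length(lines_trim)) {
    ln <- lines_trim[i]
    if (ln == "" || startsWith(ln, "data_") || ln == "loop_") break
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) != length(tags)) {
      abort(sprintf("%s: row %d has %d fields, expected %d.",
                    path, length(rows) + 1L, length(fields), length(tags)),
            class = "lamellar_parse_error")
    }
    rows[[length(rows) + 1L]] <- fields
    i <- i + 1L
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(character(), nrow = 0, ncol = length(tags))
  colnames(mat) <- tags
  as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
}

star_numeric <- function(x, tag, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    abort(sprintf("%s: non-numeric value '%s' in column %s at row %d.",
                  path, x[bad[1]], tag, bad[1]),
          class = "lamellar_parse_error")
  }
  out
}

#' Validate a particle table
#'
#' A particle table is a tibble with one row per particle: `particle_id`
#' (unique), `tomogram_id`, coordinates `x`, `y`, `z` in nm, and optional
#' annotation columns `depth_nm` (distance to the nearest milling surface)
#' and `tomo_thickness_nm` (local lamella thickness).
#'
#' @param t A data frame.
#' @return `t` as a tibble, invisibly checked.
#' @export
validate_particle_table <- function(t) {
  t <- as_tibble(t)
  need <- c("particle_id", "tomogram_id", "x", "y", "z")
  missing_cols <- setdiff(need, names(t))
  if (length(missing_cols)) {
    abort(paste0("particle table lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "lamellar_format_error")
  }
  if (anyDuplicated(t$particle_id)) {
    abort("particle_id values must be unique within a table.",
          class = "lamellar_validation_error")
  }
  if (!all(is.finite(t$x) & is.finite(t$y) & is.finite(t$z))) {
    abort("particle coordinates must be finite.", class = "lamellar_validation_error")
  }
  if ("depth_nm" %in% names(t) &&
      any(!is.na(t$depth_nm) & t$depth_nm < 0)) {
    abort("depth_nm must be >= 0 where present.", class = "lamellar_validation_error")
  }
  t
}

#' Read a RELION-dialect STAR particle table
#'
#' Reads the single loop of a STAR particle file, converting pixel
#' coordinates to nm (`nm = px * angstrom_per_px / 10`). The depth and
#' thickness annotation columns written by [write_particle_star()] are
#' recognised and mapped back to `depth_nm` / `tomo_thickness_nm`; all other
#' columns are preserved verbatim for round-tripping.
#'
#' @param path Path to the STAR file.
#' @param pixel_size Pixel size in Angstrom per pixel used to convert the
#'   stored pixel coordinates to nm.
#' @return A particle table tibble (see [validate_particle_table()]).
#' @export
read_particle_star <- function(path, pixel_size) {
  assert_positive(pixel_size, "pixel_size")
  lines <- readLines(path, warn = FALSE)
  raw <- parse_star_loop(lines, path)
  need <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ", "rlnMicrographName")
  for (tag in need) {
    if (!tag %in% names(raw)) {
      abort(sprintf("%s: mandatory column %s is missing.", path, tag),
            class = "lamellar_format_error")
    }
  }
  nm_per_px <- pixel_size / 10
  out <- tibble(
    particle_id = if ("rlnImageName" %in% names(raw)) raw$rlnImageName else
      sprintf("p%06d", seq_len(nrow(raw))),
    tomogram_id = raw$rlnMicrographName,
    x = star_numeric(raw$rlnCoordinateX, "rlnCoordinateX", path) * nm_per_px,
    y = star_numeric(raw$rlnCoordinateY, "rlnCoordinateY", path) * nm_per_px,
    z = star_numeric(raw$rlnCoordinateZ, "rlnCoordinateZ", path) * nm_per_px
  )
  if (DEPTH_TAG %in% names(raw)) {
    out$depth_nm <- star_numeric(raw[[DEPTH_TAG]], DEPTH_TAG, path)
  }
  if (THICKNESS_TAG %in% names(raw)) {
    out$tomo_thickness_nm <- star_numeric(raw[[THICKNESS_TAG]], THICKNESS_TAG, path)
  }
  known <- c("rlnImageName", "rlnMicrographName", "rlnCoordinateX",
             "rlnCoordinateY", "rlnCoordinateZ", DEPTH_TAG, THICKNESS_TAG)
  for (tag in setdiff(names(raw), known)) out[[tag]] <- raw[[tag]]
  if (nrow(out) == 0L) {
    out$particle_id <- character(); out$tomogram_id <- character()
  }
  validate_particle_table(out)
}

star_format <- function(x) {
  if (is.numeric(x)) sprintf("%.15g", x) else as.character(x)
}

#' Write a particle table as a RELION-dialect STAR file
#'
#' Coordinates are converted nm -> pixels with the given pixel size and
#' written to rlnCoordinateX/Y/Z; `depth_nm` and `tomo_thickness_nm` become
#' the custom columns `lamellarDepthNm` / `lamellarThicknessNm` when present.
#' Extra columns are appended under their own names. Numeric values are
#' printed with 15 significant digits so a write/read cycle is lossless to
#' better than 1e-9 relative.
#'
#' @param t A particle table.
#' @inheritParams read_particle_star
#' @return `path`, invisibly.
#' @export
write_particle_star <- function(t, path, pixel_size) {
  t <- validate_particle_table(t)
  assert_positive(pixel_size, "pixel_size")
  px_per_nm <- 10 / pixel_size
  cols <- list(
    rlnCoordinateX = star_format(t$x * px_per_nm),
    rlnCoordinateY = star_format(t$y * px_per_nm),
    rlnCoordinateZ = star_format(t$z * px_per_nm),
    rlnMicrographName = as.character(t$tomogram_id),
    rlnImageName = as.character(t$particle_id)
  )
  if ("depth_nm" %in% names(t)) cols[[DEPTH_TAG]] <- star_format(t$depth_nm)
  if ("tomo_thickness_nm" %in% names(t)) cols[[THICKNESS_TAG]] <- star_format(t$tomo_thickness_nm)
  std <- c("particle_id", "tomogram_id", "x", "y", "z", "depth_nm", "tomo_thickness_nm")
  for (extra in setdiff(names(t), std)) cols[[extra]] <- star_format(t[[extra]])
  header <- c(
    "", "data_particles", "", "loop_",
    sprintf("_%s #%d", names(cols), seq_along(cols))
  )
  rows <- if (nrow(t)) do.call(paste, c(cols, sep = "\t")) else character()
  writeLines(c(header, rows, ""), path)
  invisible(path)
}
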