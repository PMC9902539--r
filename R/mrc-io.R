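## MRC2014 mode-2 (32-bit float) volume I/O.
##
## Only the fields the pipeline needs are interpreted: grid dimensions,
## mode, cell dimensions (voxel size = cell / grid), and the map/machine
## stamps. Little-endian throughout; the reader rejects other modes.

#' Construct a voxel volume
#'
#' Carrier for 3D scalar maps (sub-volumes, half-maps, masks): a numeric 3D
#' array plus an isotropic voxel size in Angstrom.
#'
#' @param data Numeric 3D array (x fastest, matching MRC axis order).
#' @param voxel_size Voxel edge length in Angstrom.
#' @return Object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.", class = "lamellar_format_error")
  }
  assert_positive(voxel_size, "voxel_size")
  structure(list(data = data, voxel_size = voxel_size), class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Voxel volume %dx%dx%d at %.3g A/voxel\n", d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

assert_cubic <- function(vol) {
  d <- dim(vol$data)
  if (length(unique(d)) != 1L) {
    abort(sprintf("volume must be cubic for FSC use; got %dx%dx%d.", d[1], d[2], d[3]),
          class = "lamellar_dimension_error")
  }
  invisible(vol)
}

#' Read an MRC2014 volume
#'
#' @param path Path to an MRC file (mode 2, 32-bit float).
#' @return A [voxel_volume()]; voxel size is taken from the header cell.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  if (mode != 2L) {
    abort(sprintf("%s: MRC mode %d unsupported (only mode 2).", path, mode),
          class = "lamellar_format_error")
  }
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  invisible(readBin(con, "raw", n = 1024 - 4 * 13))  # rest of the header
  vs <- cella[1] / nx
  n <- nx * ny * nz
  data <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(data) != n) {
    abort(sprintf("%s: truncated data section.", path), class = "lamellar_format_error")
  }
  voxel_volume(array(data, dim = c(nx, ny, nz)), voxel_size = vs)
}

#' Write a volume as MRC2014 mode 2
#'
#' @param vol A [voxel_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                    # NX NY NZ
  wi(2L)                   # MODE 2 = float32
  wi(c(0L, 0L, 0L))        # NXSTART..
  wi(d)                    # MX MY MZ
  wf(d * vol$voxel_size)   # CELLA
  wf(c(90, 90, 90))        # CELLB
  wi(c(1L, 2L, 3L))        # MAPC MAPR MAPS
  stats_v <- range(vol$data)
  wf(c(stats_v[1], stats_v[2], mean(vol$data)))  # DMIN DMAX DMEAN
  wi(1L)                   # ISPG
  wi(0L)                   # NSYMBT
  writeBin(raw(100), con)  # EXTRA
  wf(c(0, 0, 0))           # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(vol$data))         # RMS
  wi(0L)                   # NLABL
  writeBin(raw(800), con)  # labels
  wf(vol$data)
  invisible(path)
}
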