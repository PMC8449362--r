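# MRC2014 volume input/output. Mode 2 (float32) is the working format; modes
# 0 (int8) and 1 (int16) are read-only conveniences. Header pixel size is
# stored in Angstrom (cella/mx) and converted to nm at the boundary --
# tables and the data model are in nm throughout.

#' Construct a tomogram volume
#'
#' The in-memory unit every pipeline stage consumes and produces: a 3D scalar
#' grid with physical pixel size and tilt-range metadata.
#' @param grid 3D numeric array, dim c(nx, ny, nz); z is the beam axis
#' @param pixel_size voxel edge in nm
#' @param tilt_range one-sided tilt range in degrees (in (0, 90])
#' @param origin nm position of voxel (1,1,1), length 3
#' @return object of class `tomogram_volume`
#' @export
tomogram_volume <- function(grid, pixel_size, tilt_range = 60,
                            origin = c(0, 0, 0)) {
  stopifnot(length(dim(grid)) == 3)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive", call. = FALSE)
  if (tilt_range <= 0 || tilt_range > 90)
    stop("tilt_range must lie in (0, 90]", call. = FALSE)
  structure(list(grid = grid, pixel_size = pixel_size,
                 tilt_range = tilt_range, origin = origin),
            class = "tomogram_volume")
}

#' @export
print.tomogram_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<tomogram_volume> %d x %d x %d voxels, %.3f nm/voxel, tilt +/-%g deg\n",
              d[1], d[2], d[3], x$pixel_size, x$tilt_range))
  invisible(x)
}

#' Write a volume as an MRC2014 file (mode 2)
#' @param vol a `tomogram_volume` or plain 3D array
#' @param path output file
#' @param pixel_size nm per voxel (taken from `vol` when it is a tomogram_volume)
#' @return `path`, invisibly
#' @export
write_mrc <- function(vol, path, pixel_size = NULL) {
  if (inherits(vol, "tomogram_volume")) {
    if (is.null(pixel_size)) pixel_size <- vol$pixel_size
    grid <- vol$grid
  } else grid <- vol
  if (is.null(pixel_size)) stop("pixel_size required for a bare array", call. = FALSE)
  d <- dim(grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2: float32
  wi(c(0L, 0L, 0L))          # nxstart nystart nzstart
  wi(d)                      # mx my mz
  wf(d * pixel_size * 10)    # cella (Angstrom)
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(grid), max(grid), mean(grid)))  # dmin dmax dmean
  wi(0L)                     # ispg
  wi(0L)                     # nsymbt
  wi(integer(25))            # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(grid))        # rms
  wi(0L)                     # nlabl
  writeBin(raw(800), con)    # labels
  writeBin(as.numeric(grid), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 volume
#' @param path MRC file
#' @param tilt_range tilt metadata to attach (not stored in the MRC header)
#' @return a `tomogram_volume`; header pixel size (Angstrom) is converted to nm
#' @export
read_mrc <- function(path, tilt_range = 60) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024)
    stop(sprintf("not an MRC file (size %s < 1024-byte header): %s", sz, path),
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)            # nxstart..
  m <- ri(3)       # mx my mz
  cella <- rf(3)
  rf(3); ri(3); rf(3); ri(2); ri(25); rf(3)
  map_tag <- readChar(con, 4, useBytes = TRUE)
  if (!identical(map_tag, "MAP ") || any(d <= 0) || any(d > 1e5))
    stop(sprintf("not an MRC2014 file (MAP tag missing at offset 208): %s", path),
         call. = FALSE)
  bytes_per <- c(`0` = 1L, `1` = 2L, `2` = 4L)[as.character(mode)]
  if (is.na(bytes_per))
    stop(sprintf("unsupported MRC mode %d (offset 12) in %s", mode, path),
         call. = FALSE)
  nvox <- prod(d)
  if (sz < 1024 + nvox * bytes_per)
    stop(sprintf("truncated MRC file (expected %d data bytes at offset 1024): %s",
                 nvox * bytes_per, path), call. = FALSE)
  seek(con, 1024)
  data <- switch(as.character(mode),
    `0` = readBin(con, "integer", n = nvox, size = 1, signed = TRUE),
    `1` = readBin(con, "integer", n = nvox, size = 2, endian = "little"),
    `2` = readBin(con, "numeric", n = nvox, size = 4, endian = "little"))
  px_nm <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] / 10 else 1
  tomogram_volume(array(as.numeric(data), d), pixel_size = px_nm,
                  tilt_range = tilt_range)
}
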