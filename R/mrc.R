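#' Read a CCP4/MRC density map
#'
#' Parses an MRC2014-style volume into a [density_grid]. The three axis-order
#' words of the header (`MAPC`, `MAPR`, `MAPS`) are honoured: on read the
#' value array is permuted into the package's single canonical order
#' (array index 1 = x, 2 = y, 3 = z), so downstream code never sees a
#' permuted volume. Voxel size is `CELLA / (MX, MY, MZ)`; the origin is taken
#' from the MRC2014 `ORIGIN` record, falling back to `N*START * voxel_size`
#' when the origin record is all-zero. Map mean and sigma are recomputed from
#' the voxel values rather than trusted from the header.
#'
#' Only orthogonal cells (all angles 90 degrees) and modes 0 (int8),
#' 1 (int16), 2 (float32) and 6 (uint16) are supported.
#'
#' @param path path to an MRC/CCP4 file.
#' @return A [density_grid].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("map file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) stop(sprintf("truncated MRC header in %s", path))

  parse_header <- function(endian) {
    ints <- readBin(hdr_raw, "integer", n = 256L, size = 4L, endian = endian)
    flts <- readBin(hdr_raw, "double", n = 256L, size = 4L, endian = endian)
    list(nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
         nstart = ints[5:7], m = ints[8:10],
         cella = flts[11:13], cellb = flts[14:16],
         mapcrs = ints[17:19], nsymbt = ints[24],
         origin = flts[50:52], endian = endian)
  }
  h <- parse_header("little")
  plausible <- function(h) {
    all(c(h$nx, h$ny, h$nz) >= 1) && all(c(h$nx, h$ny, h$nz) <= 100000L) &&
      h$mode %in% c(0L, 1L, 2L, 6L)
  }
  if (!plausible(h)) {
    h <- parse_header("big")
    if (!plausible(h)) stop(sprintf("not a readable MRC/CCP4 volume: %s", path))
  }
  if (any(abs(h$cellb - 90) > 1e-3))
    stop("unsupported geometry: non-orthogonal cell angles")
  if (!setequal(h$mapcrs, 1:3)) {
    if (all(h$mapcrs == 0L)) h$mapcrs <- 1:3 else
      stop("invalid axis-order words in MRC header")
  }

  n_vox <- as.double(h$nx) * h$ny * h$nz
  if (h$nsymbt > 0) readBin(con, "raw", n = h$nsymbt)
  vals <- switch(as.character(h$mode),
    "0" = readBin(con, "integer", n = n_vox, size = 1L, signed = TRUE, endian = h$endian),
    "1" = readBin(con, "integer", n = n_vox, size = 2L, signed = TRUE, endian = h$endian),
    "2" = readBin(con, "double",  n = n_vox, size = 4L, endian = h$endian),
    "6" = readBin(con, "integer", n = n_vox, size = 2L, signed = FALSE, endian = h$endian))
  if (length(vals) < n_vox) stop(sprintf("truncated MRC data block in %s", path))
  arr <- array(as.double(vals), dim = c(h$nx, h$ny, h$nz))

  # normalize axis order: output dim i (x,y,z) <- file dim holding that axis
  perm <- match(1:3, h$mapcrs)
  arr <- aperm(arr, perm)

  m_xyz <- ifelse(h$m > 0, h$m, dim(arr))
  voxel <- ifelse(h$cella > 0, h$cella / m_xyz, 1)
  if (all(abs(h$origin) < 1e-6) && any(h$nstart != 0L)) {
    start_xyz <- h$nstart[perm]
    origin <- start_xyz * voxel
  } else origin <- h$origin
  density_grid(arr, voxel_size = voxel, origin = origin)
}

#' Write a density grid as an MRC2014 volume
#'
#' Volumes are written as mode 2 (float32), little endian, with `MAPC/R/S`
#' equal to `axis_order` (default 1,2,3, i.e. x fastest). The origin is stored
#' in the MRC2014 `ORIGIN` record. A file written by `write_map()` reads back
#' with identical values, voxel size and origin (float32 precision).
#'
#' @param grid a [density_grid].
#' @param path output file path.
#' @param axis_order internal permutation written to the `MAPC/R/S` words;
#'   non-default orders exist to exercise the axis-normalization contract of
#'   [read_map()].
#' @return Invisibly, `path`.
#' @export
write_map <- function(grid, path, axis_order = c(1L, 2L, 3L)) {
  check_grid(grid)
  if (!setequal(axis_order, 1:3)) stop("axis_order must be a permutation of 1:3")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("cannot write map: directory %s does not exist", dir))
  # file dim j holds axis axis_order[j]; aperm so file order is (c,r,s)
  arr <- aperm(grid$values, axis_order)
  d_file <- dim(arr)
  d_xyz <- dim(grid$values)

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d_file)                               # NX NY NZ (file order)
  wi(2L)                                   # MODE float32
  wi(c(0L, 0L, 0L))                        # NXSTART
  wi(d_xyz)                                # MX MY MZ (cell sampling, xyz)
  wf(d_xyz * grid$voxel_size)              # CELLA
  wf(c(90, 90, 90))                        # CELLB
  wi(axis_order)                           # MAPC MAPR MAPS
  wf(c(min(grid$values), max(grid$values), grid$mean))
  wi(c(1L, 0L))                            # ISPG, NSYMBT
  writeBin(raw(8L), con)                   # EXTRA 25-26
  writeChar("MRCO", con, nchars = 4L, eos = NULL)  # EXTTYP
  wi(20140L)                               # NVERSION
  writeBin(raw(4L * 21L), con)             # EXTRA 29-49
  wf(grid$origin)                          # ORIGIN (xyz)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little endian
  wf(grid$sigma)                           # RMS
  wi(0L)                                   # NLABL
  writeBin(raw(800L), con)                 # LABELS
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(path)
}
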