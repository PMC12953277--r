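# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package is available in the target R stack, so the subset of the
# format actually produced by this package (and by nibabel defaults) is
# implemented directly: 348-byte NIfTI-1 headers, magic "n+1", scalar
# datatypes, both endiannesses on read, gzip transparently via gzfile().

NIFTI_DATATYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into a
#' [ct_volume()]. Spacing is taken from `pixdim`, the origin from the sform
#' translation column when `sform_code > 0`, else from the qform offsets.
#' Rotational parts of the affine are ignored: volumes are used here as
#' axis-aligned grids.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("corrupt NIfTI file (short header): ", path)

  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unrecognized NIfTI magic string in ", path)
  if (magic == "ni1")
    stop("two-file NIfTI (.hdr/.img) is not supported: ", path)

  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1L):(off + n * size)], what,
            n = n, size = size, endian = endian)
  }
  dims <- rd(40L, "integer", 8L, 2L)
  ndim <- dims[1]
  if (ndim < 2L || ndim > 4L)
    stop("unsupported NIfTI dimensionality: ", ndim)
  shape <- dims[2:(1 + ndim)]
  if (ndim == 4L) {
    if (shape[4] != 1L) stop("4D NIfTI with >1 volume is not supported")
    shape <- shape[1:3]
  }
  if (ndim == 2L) shape <- c(shape, 1L)

  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  qform_code <- rd(252L, "integer", 1L, 2L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  qoffset <- rd(268L, "double", 3L, 4L)
  srow <- matrix(rd(280L, "double", 12L, 4L), nrow = 3L, byrow = TRUE)

  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip < 0L) stop("invalid vox_offset in ", path)
  if (skip > 0L) readBin(con, "raw", n = skip)
  nvox <- prod(shape)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != nvox) stop("corrupt NIfTI file (short data): ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  spacing <- abs(pixdim[2:4])
  origin <- if (sform_code > 0L) srow[, 4] else if (qform_code > 0L) qoffset
            else c(0, 0, 0)
  ct_volume(array(as.numeric(vals), shape), spacing = spacing,
            origin = origin)
}

#' Read a NIfTI-1 binary mask
#'
#' As [read_nifti()] but validates and returns a [seg_mask()]. Any strictly
#' positive voxel is treated as foreground (tolerates masks stored with a
#' nonzero label value).
#'
#' @param path Path to a `.nii` or `.nii.gz` mask file.
#' @return A [seg_mask()].
#' @export
read_nifti_mask <- function(path) {
  v <- read_nifti(path)
  seg_mask((v$data > 0) + 0L, spacing = v$spacing, origin = v$origin)
}

#' Write a NIfTI-1 volume or mask
#'
#' Writes a [ct_volume()] or [seg_mask()] as a single-file NIfTI-1 image,
#' gzip-compressed when `path` ends in `.gz`. Masks and other integer grids
#' in \[0, 255\] are stored as uint8, everything else as float32.
#'
#' @param x A [ct_volume()] or [seg_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  stopifnot(inherits(x, "ct_volume") || inherits(x, "seg_mask"))
  data <- x$data
  shape <- dim(data)
  as_u8 <- all(data == round(data)) && min(data) >= 0 && max(data) <= 255
  datatype <- if (as_u8) 2L else 16L
  bitpix <- if (as_u8) 8L else 32L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wI <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wF <- function(v) writeBin(as.numeric(v), con, size = 4L,
                             endian = "little")
  zeros <- function(n) writeBin(raw(n), con)

  wI(348L, 4L)                       # sizeof_hdr
  zeros(28L)                         # data_type, db_name
  wI(0L, 4L); wI(0L, 2L); zeros(2L)  # extents, session_error, regular+dim_info
  wI(c(3L, shape, 1L, 1L, 1L, 1L), 2L)           # dim[8]
  wF(c(0, 0, 0)); wI(0L, 2L)                     # intent_p1..3, intent_code
  wI(datatype, 2L); wI(bitpix, 2L); wI(0L, 2L)   # datatype, bitpix, slice_start
  wF(c(1, x$spacing, 0, 0, 0, 0))                # pixdim[8], qfac = 1
  wF(352); wF(1); wF(0)              # vox_offset, scl_slope, scl_inter
  wI(0L, 2L); zeros(1L)              # slice_end, slice_code
  writeBin(as.raw(2L), con)          # xyzt_units: mm
  wF(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  wI(c(0L, 0L), 4L)                  # glmax, glmin
  zeros(104L)                        # descrip, aux_file
  wI(0L, 2L); wI(1L, 2L)             # qform_code, sform_code
  wF(c(0, 0, 0))                     # quatern b, c, d
  wF(x$origin)                       # qoffset x, y, z
  wF(c(x$spacing[1], 0, 0, x$origin[1]))
  wF(c(0, x$spacing[2], 0, x$origin[2]))
  wF(c(0, 0, x$spacing[3], x$origin[3]))
  zeros(16L)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)    # magic
  zeros(4L)                          # extender

  if (as_u8) wI(as.vector(data), 1L) else wF(as.vector(data))
  invisible(path)
}
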