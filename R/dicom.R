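# Minimal DICOM series reader: uncompressed single-frame CT slices in
# implicit or explicit VR little endian. Only the handful of tags needed to
# geometrically assemble a volume are interpreted; everything else is
# skipped by length. Sequences with undefined length are not supported.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

DCM_WANTED <- c(
  "0008,0018",  # SOPInstanceUID
  "0020,0032",  # ImagePositionPatient
  "0020,0037",  # ImageOrientationPatient
  "0028,0010",  # Rows
  "0028,0011",  # Columns
  "0028,0030",  # PixelSpacing
  "0028,0100",  # BitsAllocated
  "0028,0103",  # PixelRepresentation
  "0028,1052",  # RescaleIntercept
  "0028,1053",  # RescaleSlope
  "7FE0,0010"   # PixelData
)

# VRs whose explicit form carries a 2-byte reserved field + 4-byte length
DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  n <- length(raw)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2L, signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                               size = 4L, endian = "little")
  pos <- 0L
  if (n >= 132L && rawToChar(raw[129:132]) == "DICM") pos <- 132L

  elems <- list()
  explicit <- TRUE          # file meta group is always explicit
  transfer_syntax <- "1.2.840.10008.1.2.1"
  past_meta <- FALSE

  while (pos + 8L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    if (!past_meta && group != 0x0002 && pos > 0L) {
      past_meta <- TRUE
      explicit <- transfer_syntax != "1.2.840.10008.1.2"
      if (!transfer_syntax %in%
          c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop("unsupported DICOM transfer syntax ", transfer_syntax,
             " in ", path)
    }
    if (explicit || group == 0x0002) {
      vr <- rawToChar(raw[(pos + 5L):(pos + 6L)])
      if (vr %in% DCM_LONG_VRS) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == -1L || bitwAnd(len, -1L) == -1L)
      stop("undefined-length DICOM element not supported in ", path)
    start <- pos + hdr
    if (start + len > n) stop("truncated DICOM element in ", path)
    key <- dcm_tag(group, element)
    if (key %in% DCM_WANTED) {
      elems[[key]] <- list(vr = vr, bytes = raw[seq.int(start + 1L,
                                                        length.out = len)])
    }
    if (key == "0002,0010") {
      ts <- sub("\\0+$", "", rawToChar(raw[seq.int(start + 1L,
                                                   length.out = len)]))
      transfer_syntax <- trimws(ts)
    }
    pos <- start + len
  }
  elems
}

dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(sub("\\0+$", "", rawToChar(el$bytes)))
}
dcm_num_vec <- function(el) {
  s <- dcm_str(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_u16_val <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$bytes, "integer", size = 2L, signed = FALSE, endian = "little")
}

#' Read a DICOM series as a CT volume
#'
#' Reads all DICOM files in a directory, sorts slices by their position
#' along the slice normal (the cross product of the row and column
#' orientation vectors, falling back to the z component of
#' ImagePositionPatient), applies the rescale slope/intercept to obtain
#' Hounsfield units, and stacks them into a [ct_volume()]. Only uncompressed
#' implicit/explicit VR little endian single-frame images are supported.
#'
#' @param dir Directory containing one DICOM series.
#' @param pattern Optional filename regexp (default: all files).
#' @param spacing_tol Relative tolerance on inter-slice spacing consistency.
#' @return A [ct_volume()] with spacing `(row, col, slice)` in mm.
#' @export
read_dicom_series <- function(dir, pattern = NULL, spacing_tol = 0.01) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir)

  slices <- lapply(files, function(f) {
    el <- dcm_parse_file(f)
    rows <- dcm_u16_val(el[["0028,0010"]])
    cols <- dcm_u16_val(el[["0028,0011"]])
    if (is.null(rows) || is.null(cols) || is.null(el[["7FE0,0010"]]))
      stop("missing image tags in DICOM file ", f)
    bits <- dcm_u16_val(el[["0028,0100"]])
    if (is.null(bits)) bits <- 16L
    if (!bits %in% c(8L, 16L)) stop("unsupported BitsAllocated in ", f)
    pixrep <- dcm_u16_val(el[["0028,0103"]])
    signed <- !is.null(pixrep) && pixrep == 1L
    px <- readBin(el[["7FE0,0010"]]$bytes, "integer",
                  n = rows * cols, size = bits / 8L,
                  signed = if (bits == 8L) signed else signed,
                  endian = "little")
    slope <- dcm_num_vec(el[["0028,1053"]]); if (is.null(slope)) slope <- 1
    inter <- dcm_num_vec(el[["0028,1052"]]); if (is.null(inter)) inter <- 0
    ipp <- dcm_num_vec(el[["0020,0032"]])
    iop <- dcm_num_vec(el[["0020,0037"]])
    ps <- dcm_num_vec(el[["0028,0030"]])
    # PixelData is stored row-major (column index fastest); build the slice
    # so that [i, j] indexes (column i, row j).
    mat <- matrix(px * slope + inter, nrow = cols, ncol = rows)
    list(mat = mat, ipp = ipp, iop = iop, ps = ps,
         rows = rows, cols = cols, file = f)
  })

  rows <- unique(vapply(slices, `[[`, 1L, "rows"))
  cols <- unique(vapply(slices, `[[`, 1L, "cols"))
  if (length(rows) != 1L || length(cols) != 1L)
    stop("inconsistent slice dimensions across DICOM series in ", dir)

  pos <- vapply(slices, function(s) {
    if (is.null(s$ipp)) stop("missing ImagePositionPatient in ", s$file)
    if (!is.null(s$iop) && length(s$iop) == 6L) {
      normal <- c(s$iop[2] * s$iop[6] - s$iop[3] * s$iop[5],
                  s$iop[3] * s$iop[4] - s$iop[1] * s$iop[6],
                  s$iop[1] * s$iop[5] - s$iop[2] * s$iop[4])
      sum(s$ipp * normal)
    } else {
      s$ipp[3]
    }
  }, numeric(1))
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]

  nz <- length(slices)
  dz <- if (nz > 1L) diff(pos) else 1
  if (nz > 2L) {
    m <- mean(dz)
    if (any(abs(dz - m) > spacing_tol * abs(m)))
      stop("inconsistent slice spacing in DICOM series ", dir)
  }
  ps <- slices[[1]]$ps
  if (is.null(ps) || length(ps) != 2L) ps <- c(1, 1)
  data <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) data[, , k] <- slices[[k]]$mat
  origin <- slices[[1]]$ipp
  if (is.null(origin) || length(origin) != 3L) origin <- c(0, 0, 0)
  # PixelSpacing is (row spacing, column spacing): axis 1 here runs along
  # image columns, so it gets the column spacing.
  ct_volume(data, spacing = c(ps[2], ps[1], mean(dz)), origin = origin)
}

#' Load a volume from NIfTI or a DICOM series
#'
#' Dispatches on `format`: `"nifti"` expects a `.nii`/`.nii.gz` file,
#' `"dicom_series"` a directory of slices.
#'
#' @param path File (NIfTI) or directory (DICOM) path.
#' @param format `"nifti"` or `"dicom_series"`; the default guesses from
#'   whether `path` is a directory.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  switch(format,
         nifti = read_nifti(path),
         dicom_series = read_dicom_series(path))
}
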