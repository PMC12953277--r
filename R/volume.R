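#' Volumetric containers
#'
#' `ct_volume()` wraps a 3D scalar grid in Hounsfield units together with
#' its voxel spacing (mm) and physical origin. `seg_mask()` wraps a binary
#' 3D label field on the same grid convention. Voxel indices are treated as
#' cell-centred: voxel `i` (0-based) spans the half-open physical interval
#' `[origin + i*dx, origin + (i+1)*dx)` along each axis.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, voxel edge lengths in mm, all > 0.
#' @param origin Numeric length-3, physical coordinate (mm) of the corner of
#'   voxel (0,0,0). Defaults to `c(0, 0, 0)`.
#' @return An object of class `ct_volume` or `seg_mask`: a list with
#'   elements `data`, `spacing`, `origin`.
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(v$data)
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3d(data)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite numbers (mm)")
  if (any(!is.finite(data)))
    stop("volume contains non-finite voxel values")
  structure(list(data = data, spacing = spacing, origin = origin,
                 axes = "ijk"),
            class = "ct_volume")
}

#' @rdname ct_volume
#' @export
seg_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3d(data)
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1)))
    stop("mask values must all be 0 or 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite numbers (mm)")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = spacing, origin = origin,
                 axes = "ijk"),
            class = "seg_mask")
}

# Promote 2D (single slice) input to a 3D array; reject higher ranks.
as_array3d <- function(data) {
  if (is.null(dim(data))) stop("'data' must be an array")
  d <- dim(data)
  if (length(d) == 2L) {
    data <- array(data, c(d, 1L))
  } else if (length(d) != 3L) {
    stop("'data' must be a 2D or 3D array")
  }
  if (any(dim(data) < 1L)) stop("grid must have >= 1 voxel per axis")
  data
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

# Shared geometry check used by operations pairing a mask with a volume.
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}
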