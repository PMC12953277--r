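#' Resample a CT volume to an isotropic grid
#'
#' Resamples to cubic voxels of edge `target_spacing` mm by trilinear
#' interpolation, the standard harmonization step before morphometric
#' analysis of multi-scanner CT. The output shape per axis is
#' `round(extent_mm / target_spacing)` where `extent_mm = shape * spacing`;
#' grids are cell-centred, so resampling a volume to its own spacing is the
#' identity (up to float tolerance).
#'
#' @param vol A [ct_volume()].
#' @param target_spacing Positive scalar, target voxel edge in mm (default 1).
#' @param interpolation Only `"linear"` (trilinear) is implemented.
#' @return A [ct_volume()] with spacing `c(t, t, t)`.
#' @export
resample_isotropic <- function(vol, target_spacing = 1,
                               interpolation = c("linear")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.finite(target_spacing) || target_spacing <= 0)
    stop("'target_spacing' must be > 0")
  d_in <- dim(vol$data)
  if (any(d_in == 1L))
    stop("cannot resample a degenerate axis (single voxel)")
  d_out <- pmax(1L, as.integer(round(d_in * vol$spacing / target_spacing)))
  arr <- interp_trilinear(vol$data, vol$spacing, d_out,
                          rep(target_spacing, 3))
  ct_volume(arr, spacing = rep(target_spacing, 3), origin = vol$origin)
}

# Trilinear interpolation of `arr` (spacing sp_in, cell-centred) onto a grid
# of shape d_out with spacing sp_out sharing the same physical origin.
interp_trilinear <- function(arr, sp_in, d_out, sp_out) {
  d_in <- dim(arr)
  ax <- lapply(1:3, function(a) {
    # fractional source index (0-based) of each output voxel centre
    f <- ((seq_len(d_out[a]) - 0.5) * sp_out[a]) / sp_in[a] - 0.5
    f <- pmin(pmax(f, 0), d_in[a] - 1)
    i0 <- pmin(floor(f), d_in[a] - 2)
    if (d_in[a] == 1L) i0 <- rep(0, d_out[a])
    w <- f - i0
    list(i0 = as.integer(i0) + 1L, w = w)
  })
  nx <- d_out[1]; ny <- d_out[2]; nz <- d_out[3]
  i0 <- ax[[1]]$i0; j0 <- ax[[2]]$i0; k0 <- ax[[3]]$i0
  wx <- ax[[1]]$w;  wy <- ax[[2]]$w;  wz <- ax[[3]]$w
  out <- array(0, d_out)
  dx <- d_in[1]; dxy <- d_in[1] * d_in[2]
  IX <- rep.int(i0, ny * nz); WX <- rep.int(wx, ny * nz)
  IY <- rep.int(rep(j0, each = nx), nz); WY <- rep.int(rep(wy, each = nx), nz)
  IZ <- rep(k0, each = nx * ny); WZ <- rep(wz, each = nx * ny)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    ii <- pmin(IX + cx, d_in[1]); jj <- pmin(IY + cy, d_in[2])
    kk <- pmin(IZ + cz, d_in[3])
    w <- (if (cx) WX else 1 - WX) * (if (cy) WY else 1 - WY) *
         (if (cz) WZ else 1 - WZ)
    lin <- ii + (jj - 1L) * dx + (kk - 1L) * dxy
    out <- out + array(w * arr[lin], d_out)
  }
  out
}

#' Resample a mask onto a target geometry
#'
#' Nearest-neighbour resampling of a binary mask onto the grid of a target
#' volume (or an explicit isotropic spacing). Nearest neighbour is used for
#' labels because linear interpolation would break binarity.
#'
#' @param mask A [seg_mask()].
#' @param target Either a [ct_volume()] whose grid to adopt, or a positive
#'   scalar isotropic spacing in mm.
#' @return A [seg_mask()] on the target grid (strictly binary).
#' @export
resample_mask <- function(mask, target) {
  stopifnot(inherits(mask, "seg_mask"))
  if (inherits(target, "ct_volume")) {
    d_out <- dim(target$data)
    sp_out <- target$spacing
    if (any(abs(mask$origin - target$origin) > 1e-6))
      stop("mask and target volume have different origins")
  } else {
    t <- as.numeric(target)
    if (length(t) != 1L || !is.finite(t) || t <= 0)
      stop("'target' must be a ct_volume or a positive spacing")
    d_out <- pmax(1L, as.integer(round(dim(mask$data) * mask$spacing / t)))
    sp_out <- rep(t, 3)
  }
  d_in <- dim(mask$data)
  idx <- lapply(1:3, function(a) {
    f <- ((seq_len(d_out[a]) - 0.5) * sp_out[a]) / mask$spacing[a] - 0.5
    as.integer(pmin(pmax(round(f), 0), d_in[a] - 1)) + 1L
  })
  arr <- mask$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(arr) <- d_out
  seg_mask(arr, spacing = sp_out, origin = mask$origin)
}

#' Quantize HU intensities to 256 gray levels
#'
#' Clips voxel values to a Hounsfield window and maps them linearly onto the
#' integers 0..255 with `floor(255 * (v - min) / (max - min) + 0.5)`. The
#' default window (-200, 400) HU covers portal-venous abdominal soft tissue.
#'
#' @param vol A [ct_volume()].
#' @param window Length-2 numeric `(hu_min, hu_max)`, `hu_min < hu_max`.
#' @return A `quantized_volume`: list with integer `data` in \[0, 255\],
#'   `window`, `spacing`, `origin`.
#' @export
quantize_intensity <- function(vol, window = c(-200, 400)) {
  stopifnot(inherits(vol, "ct_volume"))
  if (length(window) != 2L || !all(is.finite(window)) ||
      window[1] >= window[2])
    stop("'window' must be (hu_min, hu_max) with hu_min < hu_max")
  if (any(!is.finite(vol$data))) stop("volume contains non-finite values")
  v <- pmin(pmax(vol$data, window[1]), window[2])
  q <- floor(255 * (v - window[1]) / (window[2] - window[1]) + 0.5)
  q <- array(as.integer(q), dim(vol$data))
  structure(list(data = q, window = window, spacing = vol$spacing,
                 origin = vol$origin),
            class = "quantized_volume")
}

#' Crop a volume/mask pair to the lesion bounding box
#'
#' Finds the tight bounding box of the mask foreground, expands it by
#' `margin_voxels` on every side, clips to the grid, and crops both the
#' volume and the mask to it. Intervals are half-open in voxel index space.
#'
#' @param vol A [ct_volume()] (or `NULL` to crop the mask alone).
#' @param mask A [seg_mask()] with at least one foreground voxel, same grid.
#' @param margin_voxels Non-negative integer margin.
#' @return List with elements `volume` (or `NULL`), `mask`, and `bbox`
#'   (2x3 matrix of 1-based inclusive index bounds).
#' @export
crop_to_roi <- function(vol, mask, margin_voxels = 0L) {
  stopifnot(inherits(mask, "seg_mask"))
  if (!is.null(vol)) {
    stopifnot(inherits(vol, "ct_volume"))
    if (!identical(dim(vol$data), dim(mask$data)))
      stop("volume and mask shapes differ")
  }
  if (margin_voxels < 0) stop("'margin_voxels' must be >= 0")
  margin_voxels <- as.integer(margin_voxels)
  fg <- which(mask$data == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("empty mask: no foreground voxels to crop to")
  d <- dim(mask$data)
  lo <- pmax(apply(fg, 2, min) - margin_voxels, 1L)
  hi <- pmin(apply(fg, 2, max) + margin_voxels, d)
  sl <- lapply(1:3, function(a) lo[a]:hi[a])
  new_origin <- mask$origin + (lo - 1L) * mask$spacing
  m2 <- seg_mask(mask$data[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
                 spacing = mask$spacing, origin = new_origin)
  v2 <- NULL
  if (!is.null(vol)) {
    v2 <- ct_volume(vol$data[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
                    spacing = vol$spacing, origin = new_origin)
  }
  list(volume = v2, mask = m2, bbox = rbind(lo = lo, hi = hi))
}

#' Keep the largest connected component of a mask
#'
#' Labels the foreground under 26-connectivity and returns a mask containing
#' only the largest component by voxel count; ties are broken toward the
#' component whose bounding-box origin is lexicographically smallest. Used to
#' select the main (largest) lesion when a mask contains several.
#'
#' @param mask A [seg_mask()].
#' @return A [seg_mask()] with a single connected component.
#' @export
largest_component <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  lab <- label_components(mask$data)
  if (lab$n == 0L) stop("empty mask: nothing to select")
  if (lab$n == 1L) return(mask)
  sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    keys <- vapply(best, function(b) {
      ind <- which(lab$labels == b)
      co <- arrayInd(ind, dim(mask$data))
      paste(sprintf("%09d", apply(co, 2, min)), collapse = "")
    }, character(1))
    best <- best[order(keys)][1]
  } else {
    best <- best[1]
  }
  out <- array(0L, dim(mask$data))
  out[lab$labels == best] <- 1L
  seg_mask(out, spacing = mask$spacing, origin = mask$origin)
}

# Connected-component labelling (26-connectivity) by frontier expansion.
# Returns list(labels = integer array, n = number of components).
label_components <- function(arr) {
  d <- dim(arr)
  labels <- array(0L, d)
  fg <- which(arr == 1L)
  if (length(fg) == 0L) return(list(labels = labels, n = 0L))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  n <- 0L
  remaining <- fg
  isfg <- array(FALSE, d); isfg[fg] <- TRUE
  while (length(remaining) > 0L) {
    n <- n + 1L
    seed <- remaining[1]
    labels[seed] <- n
    frontier <- matrix(arrayInd(seed, d), ncol = 3)
    while (nrow(frontier) > 0L) {
      cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
        sweep(frontier, 2, offs[r, ], "+")))
      keep <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
              cand[, 2] >= 1L & cand[, 2] <= d[2] &
              cand[, 3] >= 1L & cand[, 3] <= d[3]
      cand <- cand[keep, , drop = FALSE]
      lin <- unique(cand[, 1] + (cand[, 2] - 1L) * d[1] +
                    (cand[, 3] - 1L) * d[1] * d[2])
      lin <- lin[isfg[lin] & labels[lin] == 0L]
      labels[lin] <- n
      frontier <- arrayInd(lin, d)
      if (!is.matrix(frontier)) frontier <- matrix(frontier, ncol = 3)
    }
    remaining <- remaining[labels[remaining] == 0L]
  }
  list(labels = labels, n = n)
}
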