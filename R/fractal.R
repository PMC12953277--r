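#' Box-size schedule for box counting
#'
#' Builds the ascending list of box edge lengths (in voxels) used by the
#' box-counting estimator. `pow2` yields 1, 2, 4, ... up to the largest
#' power of two not exceeding `min(shape) / 2`; `ternary` yields 1, 3, 9,
#' ... up to `min(shape)` (so a level-L Menger sponge of side `3^L` is
#' covered exactly at every scheduled scale).
#'
#' @param shape Integer vector of grid dimensions (typically the foreground
#'   bounding-box shape), all >= 2.
#' @param scheme `"pow2"`, `"ternary"`, or `"custom"`.
#' @param sizes Ascending positive integers, required when
#'   `scheme = "custom"`.
#' @return Integer vector of box sizes (length >= 2).
#' @export
box_size_schedule <- function(shape, scheme = c("pow2", "ternary", "custom"),
                              sizes = NULL) {
  scheme <- match.arg(scheme)
  m <- min(shape)
  if (m < 2) stop("grid too small for box counting (min dimension < 2)")
  s <- switch(scheme,
    pow2 = {
      top <- floor(m / 2)
      if (top >= 1) 2^(0:floor(log2(top))) else integer(0)
    },
    ternary = 3^(0:floor(log(m + 1e-9) / log(3))),
    custom = {
      if (is.null(sizes)) stop("'sizes' required for a custom schedule")
      sizes <- as.integer(sizes)
      if (any(sizes < 1) || is.unsorted(sizes, strictly = TRUE))
        stop("custom sizes must be strictly ascending positive integers")
      sizes[sizes <= m]
    })
  s <- as.integer(s)
  if (length(s) < 2L)
    stop("schedule has fewer than 2 usable box sizes for shape ",
         paste(shape, collapse = "x"))
  s
}

# Core counter on a logical/integer array: number of s-sided half-open boxes,
# anchored at the foreground bounding-box minimum corner, that contain at
# least one foreground voxel. Partial boxes at the far edges count.
box_count_array <- function(arr, s) {
  fg <- which(arr == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("empty mask: cannot count boxes")
  if (s < 1) stop("box size must be >= 1")
  lo <- c(min(fg[, 1]), min(fg[, 2]), min(fg[, 3]))
  b <- floor(sweep(fg, 2, lo) / s)
  k1 <- max(b[, 1]) + 1
  k2 <- max(b[, 2]) + 1
  key <- b[, 1] + k1 * (b[, 2] + k2 * b[, 3])
  length(unique(key))
}

#' Count occupied boxes at one scale
#'
#' Covers the mask foreground with a grid of `s x s x s` half-open boxes
#' anchored at the minimum corner of the foreground bounding box and counts
#' the boxes containing at least one foreground voxel. Anchoring at the
#' bounding box makes the count translation invariant.
#'
#' @param mask A [seg_mask()] with at least one foreground voxel.
#' @param s Box edge length in voxels (>= 1).
#' @return Integer count of occupied boxes.
#' @export
count_boxes <- function(mask, s) {
  stopifnot(inherits(mask, "seg_mask"))
  box_count_array(mask$data, s)
}

#' Box-counting curve
#'
#' Evaluates [count_boxes()] over a schedule of box sizes. Once the count
#' saturates at 1, later scales carry no information; entries with `N = 1`
#' beyond the first such size are dropped.
#'
#' @param mask A [seg_mask()].
#' @param schedule Ascending integer box sizes (length >= 2), e.g. from
#'   [box_size_schedule()].
#' @return A `box_count_curve`: list with `sizes`, `counts`,
#'   `anchor = "bbox"`.
#' @export
boxcount_curve <- function(mask, schedule) {
  stopifnot(inherits(mask, "seg_mask"))
  schedule <- as.integer(schedule)
  if (length(schedule) < 2L) stop("schedule needs >= 2 sizes")
  if (is.unsorted(schedule, strictly = TRUE))
    stop("schedule must be strictly ascending")
  counts <- vapply(schedule, function(s) box_count_array(mask$data, s),
                   numeric(1))
  first_one <- which(counts == 1)[1]
  if (!is.na(first_one) && first_one < length(counts)) {
    keep <- seq_len(first_one)
    schedule <- schedule[keep]
    counts <- counts[keep]
  }
  structure(list(sizes = schedule, counts = counts, anchor = "bbox"),
            class = "box_count_curve")
}

#' @export
print.box_count_curve <- function(x, ...) {
  cat("<box_count_curve>\n")
  print(data.frame(size = x$sizes, count = x$counts))
  invisible(x)
}

#' Fit the fractal dimension from a box-counting curve
#'
#' Ordinary least squares of `log N(s)` on `log(1/s)`; the slope is the
#' (Minkowski-Bouligand) fractal dimension estimate. Saturated entries
#' (`N = 1`) are excluded from the fit because the flat tail biases the
#' slope. `best_window` instead searches all contiguous sub-ranges of at
#' least `min_points` scales and keeps the one maximizing R^2 (ties: more
#' points, then smaller scales).
#'
#' @param curve A `box_count_curve` from [boxcount_curve()].
#' @param fit_policy `"all"` or `"best_window"`.
#' @param min_points Minimum scales per window for `best_window` (>= 3).
#' @return A `fractal_result`: list with `fd`, `intercept`, `r_squared`,
#'   `fit_sizes`, `n_points`, `flagged`, `reason`.
#' @export
fit_fractal_dimension <- function(curve, fit_policy = c("all", "best_window"),
                                  min_points = 3L) {
  fit_policy <- match.arg(fit_policy)
  stopifnot(inherits(curve, "box_count_curve"))
  keep <- curve$counts > 1
  sizes <- curve$sizes[keep]
  counts <- curve$counts[keep]
  flag <- function(reason) {
    structure(list(fd = NA_real_, intercept = NA_real_,
                   r_squared = NA_real_, fit_sizes = integer(0),
                   n_points = 0L, flagged = TRUE, reason = reason),
              class = "fractal_result")
  }
  if (length(sizes) < 2L) return(flag("fewer than 2 usable scales"))
  if (length(unique(counts)) == 1L)
    return(flag("degenerate curve: all box counts equal"))

  ols <- function(ss, nn) {
    x <- log(1 / ss); y <- log(nn)
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    icpt <- fit$coefficients[1]
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) max(0, 1 - ssr / sst) else NA_real_
    list(fd = unname(slope), intercept = unname(icpt), r2 = r2)
  }
  if (fit_policy == "all") {
    f <- ols(sizes, counts)
    use <- sizes
  } else {
    min_points <- max(3L, as.integer(min_points))
    if (length(sizes) < min_points)
      return(flag("fewer scales than 'min_points'"))
    best <- NULL
    for (len in length(sizes):min_points) {
      for (start in 1:(length(sizes) - len + 1L)) {
        idx <- start:(start + len - 1L)
        if (length(unique(counts[idx])) == 1L) next
        g <- ols(sizes[idx], counts[idx])
        if (is.null(best) || g$r2 > best$f$r2 + 1e-12) {
          best <- list(f = g, idx = idx)
        }
      }
    }
    if (is.null(best)) return(flag("no non-degenerate window"))
    f <- best$f
    use <- sizes[best$idx]
  }
  structure(list(fd = f$fd, intercept = f$intercept, r_squared = f$r2,
                 fit_sizes = use, n_points = length(use),
                 flagged = FALSE, reason = NA_character_),
            class = "fractal_result")
}

#' @export
print.fractal_result <- function(x, ...) {
  if (x$flagged) {
    cat("<fractal_result> flagged:", x$reason, "\n")
  } else {
    cat(sprintf("<fractal_result> fd = %.4f (r2 = %.4f, %d scales: %s)\n",
                x$fd, x$r_squared, x$n_points,
                paste(x$fit_sizes, collapse = ",")))
  }
  invisible(x)
}

#' Local fractal dimension map
#'
#' Slides a cubic window across the mask and estimates the box-counting
#' dimension inside each window containing foreground; windows without
#' foreground (or with too few usable scales) are marked invalid (`NA`).
#' `fd_max`, the maximum over valid windows, summarizes the most complex
#' local region of the lesion.
#'
#' @param mask A [seg_mask()].
#' @param window Cubic window edge in voxels (must fit in every dimension).
#' @param stride Window step in voxels (>= 1).
#' @param scheme Box-size schedule scheme for the per-window fits.
#' @return A `local_fd_map`: list with 3D array `map` (NA = invalid),
#'   `window`, `stride`, `fd_max`.
#' @export
local_fd_map <- function(mask, window = 32L, stride = 16L, scheme = "pow2") {
  stopifnot(inherits(mask, "seg_mask"))
  d <- dim(mask$data)
  window <- as.integer(window); stride <- as.integer(stride)
  if (stride < 1L) stop("'stride' must be >= 1")
  if (any(window > d)) stop("'window' exceeds a mask dimension")
  nw <- floor((d - window) / stride) + 1L
  map <- array(NA_real_, nw)
  schedule <- box_size_schedule(rep(window, 3), scheme)
  for (kz in seq_len(nw[3])) for (ky in seq_len(nw[2]))
    for (kx in seq_len(nw[1])) {
      x0 <- (kx - 1L) * stride; y0 <- (ky - 1L) * stride
      z0 <- (kz - 1L) * stride
      sub <- mask$data[(x0 + 1L):(x0 + window),
                       (y0 + 1L):(y0 + window),
                       (z0 + 1L):(z0 + window), drop = FALSE]
      if (!any(sub == 1L)) next
      counts <- vapply(schedule, function(s) box_count_array(sub, s),
                       numeric(1))
      cv <- structure(list(sizes = schedule, counts = counts,
                           anchor = "bbox"), class = "box_count_curve")
      fit <- fit_fractal_dimension(cv, "all")
      if (!fit$flagged) map[kx, ky, kz] <- fit$fd
    }
  if (all(is.na(map)))
    stop("no valid window: mask has no foreground inside any window")
  structure(list(map = map, window = window, stride = stride,
                 fd_max = max(map, na.rm = TRUE)),
            class = "local_fd_map")
}

#' Grayscale (differential) box-counting dimension
#'
#' Experimental variant operating on quantized intensities inside the mask
#' rather than on the binary mask: for each scale `s` the foreground
#' bounding box is tiled with `s x s x s` columns and each occupied box
#' contributes `floor(gmax/h) - floor(gmin/h) + 1` boxes of intensity height
#' `h = s * 256 / L` (`L` = longest bounding-box side). This is not the
#' primary study metric; the binary [boxcount_curve()] is.
#'
#' @param qvol A `quantized_volume` from [quantize_intensity()].
#' @param mask A [seg_mask()] on the same grid.
#' @param schedule Ascending integer box sizes.
#' @return A `fractal_result`.
#' @export
fd_grayscale <- function(qvol, mask, schedule = NULL) {
  stopifnot(inherits(qvol, "quantized_volume"), inherits(mask, "seg_mask"))
  if (!identical(dim(qvol$data), dim(mask$data)))
    stop("quantized volume and mask shapes differ")
  fg <- which(mask$data == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("empty mask")
  lo <- apply(fg, 2, min); hi <- apply(fg, 2, max)
  bb <- hi - lo + 1L
  if (is.null(schedule)) schedule <- box_size_schedule(bb, "pow2")
  L <- max(bb)
  vals <- qvol$data[fg]
  counts <- vapply(schedule, function(s) {
    h <- s * 256 / L
    b <- floor(sweep(fg, 2, lo) / s)
    key <- b[, 1] + (max(b[, 1]) + 1) * (b[, 2] + (max(b[, 2]) + 1) * b[, 3])
    gmin <- tapply(vals, key, min)
    gmax <- tapply(vals, key, max)
    sum(floor(gmax / h) - floor(gmin / h) + 1)
  }, numeric(1))
  cv <- structure(list(sizes = as.integer(schedule), counts = counts,
                       anchor = "bbox"), class = "box_count_curve")
  fit_fractal_dimension(cv, "all")
}

#' Default configuration for [compute_fd()]
#'
#' @param target_spacing_mm Isotropic resampling target (mm).
#' @param hu_window HU window for [quantize_intensity()].
#' @param crop_margin Bounding-box margin in voxels.
#' @param schedule Box-size scheme (`"pow2"` or `"ternary"`).
#' @param fit Fit policy (`"all"` or `"best_window"`).
#' @param min_points Minimum window length for `best_window`.
#' @param local_window,local_stride Local FD map geometry (voxels). The
#'   window shrinks to the largest power of two that fits small lesions.
#' @param grayscale If `TRUE`, also compute the differential variant
#'   (requires a volume).
#' @return Named list of settings.
#' @export
fd_config <- function(target_spacing_mm = 1, hu_window = c(-200, 400),
                      crop_margin = 4L, schedule = "pow2", fit = "all",
                      min_points = 3L, local_window = 32L,
                      local_stride = 16L, grayscale = FALSE) {
  list(target_spacing_mm = target_spacing_mm, hu_window = hu_window,
       crop_margin = crop_margin, schedule = schedule, fit = fit,
       min_points = min_points, local_window = local_window,
       local_stride = local_stride, grayscale = grayscale)
}

#' End-to-end fractal dimension of one lesion
#'
#' Full per-patient path: load the mask (and optionally the CT volume),
#' resample to an isotropic grid (nearest neighbour for the mask, trilinear
#' for the volume), crop to the lesion bounding box, compute the
#' box-counting curve, fit the global FD, and compute the local FD map and
#' its maximum. Deterministic: the same inputs always give the same row.
#'
#' @param volume_path NIfTI path or DICOM directory, or `NULL` (mask-only).
#' @param mask_path NIfTI mask path.
#' @param config Settings from [fd_config()].
#' @param patient_id Identifier copied into the output row.
#' @return List with `result` (`fractal_result`), `local` (`local_fd_map`
#'   or `NULL`), `grayscale` (`fractal_result` or `NULL`), and `row` (a
#'   one-row `data.frame`: `patient_id, fd, fd_max, r2, n_scales, voxels`).
#' @export
compute_fd <- function(volume_path = NULL, mask_path, config = fd_config(),
                       patient_id = "case") {
  mask <- tryCatch(read_nifti_mask(mask_path),
                   error = function(e) stop("failed to read mask '",
                                            mask_path, "': ",
                                            conditionMessage(e)))
  if (sum(mask$data) == 0L)
    stop("empty mask in file: ", mask_path)
  t <- config$target_spacing_mm
  if (any(abs(mask$spacing - t) > 1e-9)) mask <- resample_mask(mask, t)
  vol <- NULL
  if (!is.null(volume_path)) {
    vol <- load_volume(volume_path)
    if (any(abs(vol$spacing - t) > 1e-9)) vol <- resample_isotropic(vol, t)
    if (!identical(dim(vol$data), dim(mask$data)))
      stop("volume and mask disagree after resampling: ",
           paste(dim(vol$data), collapse = "x"), " vs ",
           paste(dim(mask$data), collapse = "x"))
  }
  cropped <- crop_to_roi(vol, mask, config$crop_margin)
  mask <- cropped$mask
  bb <- apply(which(mask$data == 1L, arr.ind = TRUE), 2, range)
  bb_shape <- bb[2, ] - bb[1, ] + 1L
  schedule <- box_size_schedule(bb_shape, config$schedule)
  curve <- boxcount_curve(mask, schedule)
  result <- fit_fractal_dimension(curve, config$fit, config$min_points)

  d <- dim(mask$data)
  w <- min(config$local_window, 2^floor(log2(min(d))))
  local <- NULL
  fd_max <- NA_real_
  if (w >= 4L) {
    stride <- max(1L, min(config$local_stride, as.integer(w / 2)))
    local <- local_fd_map(mask, window = as.integer(w), stride = stride,
                          scheme = config$schedule)
    fd_max <- local$fd_max
  }
  gs <- NULL
  if (isTRUE(config$grayscale)) {
    if (is.null(vol)) stop("grayscale FD requires a volume")
    q <- quantize_intensity(cropped$volume, config$hu_window)
    gs <- fd_grayscale(q, mask)
  }
  row <- data.frame(patient_id = patient_id,
                    fd = result$fd,
                    fd_max = fd_max,
                    r2 = result$r_squared,
                    n_scales = result$n_points,
                    voxels = sum(mask$data),
                    stringsAsFactors = FALSE)
  list(result = result, local = local, grayscale = gs, row = row)
}
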