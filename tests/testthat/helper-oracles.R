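# Independent oracles used across the suite. These deliberately take the
# slow, obvious route (triple loops, exhaustive pair counts) so they share
# no code path with the implementation they check.

# Naive box scanner: walk every s-box of the grid anchored at the
# foreground bounding-box minimum corner and test occupancy directly.
naive_box_count <- function(arr, s) {
  fg <- which(arr == 1L, arr.ind = TRUE)
  stopifnot(nrow(fg) > 0L)
  lo <- c(min(fg[, 1]), min(fg[, 2]), min(fg[, 3]))
  hi <- c(max(fg[, 1]), max(fg[, 2]), max(fg[, 3]))
  count <- 0L
  for (z0 in seq(lo[3], hi[3], by = s))
    for (y0 in seq(lo[2], hi[2], by = s))
      for (x0 in seq(lo[1], hi[1], by = s)) {
        sub <- arr[x0:min(x0 + s - 1L, hi[1]),
                   y0:min(y0 + s - 1L, hi[2]),
                   z0:min(z0 + s - 1L, hi[3])]
        if (any(sub == 1L)) count <- count + 1L
      }
  count
}

# Mann-Whitney AUC by exhaustive pair counting with half credit for ties.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Youden J by exhaustive search over every partition of the sorted scores
# (thresholds at each observed value and above the maximum).
brute_youden <- function(scores, labels) {
  cand <- c(sort(unique(scores)), max(scores) + 1)
  best <- -Inf
  for (t in cand) {
    pred <- scores >= t
    j <- sum(pred & labels == 1) / sum(labels == 1) +
      sum(!pred & labels == 0) / sum(labels == 0) - 1
    if (j > best) best <- j
  }
  best
}

# Global FD of a mask: bounding-box schedule + all-scales fit, as the
# pipeline computes it. `shape` overrides the schedule's reference shape
# (needed for thin phantoms whose bounding box degenerates along an axis).
mask_fd <- function(mask, scheme = "pow2", shape = NULL) {
  if (is.null(shape)) {
    fg <- which(mask$data == 1L, arr.ind = TRUE)
    bb <- apply(fg, 2, range)
    shape <- bb[2, ] - bb[1, ] + 1L
  }
  sched <- box_size_schedule(shape, scheme)
  fit_fractal_dimension(boxcount_curve(mask, sched), "all")$fd
}

# Minimal explicit-VR little-endian DICOM writer for fixture slices.
write_dicom_slice <- function(path, pixels, rows, cols, ipp,
                              pixel_spacing = c(0.7, 0.7),
                              intercept = -1024, slope = 1) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  # DICOM pads odd-length values to even: UI with NUL, text VRs with space
  padded <- function(s, vr) {
    b <- charToRaw(s)
    if (length(b) %% 2 == 1)
      b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
    b
  }
  welem <- function(group, elem, vr, bytes) {
    writeBin(as.integer(c(group, elem)), con, size = 2L, endian = "little")
    writeBin(charToRaw(vr), con)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      writeBin(raw(2L), con)
      writeBin(length(bytes), con, size = 4L, endian = "little")
    } else {
      writeBin(length(bytes), con, size = 2L, endian = "little")
    }
    writeBin(bytes, con)
  }
  ts <- padded("1.2.840.10008.1.2.1", "UI")
  welem(0x0002, 0x0000, "UL",
        writeBin(8L + length(ts), raw(), size = 4L, endian = "little"))
  welem(0x0002, 0x0010, "UI", ts)
  welem(0x0008, 0x0018, "UI", padded("1.2.3.4", "UI"))
  welem(0x0020, 0x0032, "DS",
        padded(paste(sprintf("%.4f", ipp), collapse = "\\"), "DS"))
  welem(0x0020, 0x0037, "DS",
        padded("1.0000\\0.0000\\0.0000\\0.0000\\1.0000\\0.0000", "DS"))
  welem(0x0028, 0x0010, "US",
        writeBin(as.integer(rows), raw(), size = 2L, endian = "little"))
  welem(0x0028, 0x0011, "US",
        writeBin(as.integer(cols), raw(), size = 2L, endian = "little"))
  welem(0x0028, 0x0030, "DS",
        padded(paste(sprintf("%.4f", pixel_spacing), collapse = "\\"),
               "DS"))
  welem(0x0028, 0x0100, "US",
        writeBin(16L, raw(), size = 2L, endian = "little"))
  welem(0x0028, 0x0103, "US",
        writeBin(0L, raw(), size = 2L, endian = "little"))
  welem(0x0028, 0x1052, "DS", padded(sprintf("%.1f", intercept), "DS"))
  welem(0x0028, 0x1053, "DS", padded(sprintf("%.1f", slope), "DS"))
  welem(0x7FE0, 0x0010, "OW",
        writeBin(as.integer(pixels), raw(), size = 2L, endian = "little"))
  invisible(path)
}

# Product-limit survival by direct hand computation at given times.
hand_km <- function(times, events, at) {
  s <- 1
  for (t in sort(unique(times[events == 1]))) {
    if (t > at) break
    n <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n)
  }
  s
}
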