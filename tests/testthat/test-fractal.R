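# Box counting, schedules, log-log fits, local maps, end-to-end path.

test_that("box size schedules follow their definitions", {
  expect_identical(box_size_schedule(c(64, 64, 64), "pow2"),
                   c(1L, 2L, 4L, 8L, 16L, 32L))
  expect_identical(box_size_schedule(c(27, 27, 27), "ternary"),
                   c(1L, 3L, 9L, 27L))
  expect_error(box_size_schedule(c(2, 2, 2), "pow2"), "fewer than 2")
  expect_identical(box_size_schedule(c(40, 40, 40), "custom",
                                     sizes = c(1, 5, 50)),
                   c(1L, 5L))
})

test_that("count_boxes matches closed forms on exact phantoms", {
  m2 <- make_phantom("menger", 2)
  expect_identical(count_boxes(m2, 3), 20L)
  cube8 <- make_phantom("cube", 8)
  expect_identical(count_boxes(cube8, 2), 64L)
  single <- array(0L, c(9, 9, 9)); single[4, 5, 6] <- 1L
  for (s in c(1, 2, 5)) expect_identical(count_boxes(seg_mask(single), s), 1L)
  expect_error(count_boxes(seg_mask(array(0L, c(3, 3, 3))), 1), "empty")
})

test_that("count_boxes equals the naive scanner on random masks", {
  set.seed(42)
  for (rep in 1:25) {
    arr <- array(as.integer(stats::runif(20^3) < stats::runif(1, 0.02, 0.4)),
                 c(20, 20, 20))
    if (!any(arr == 1L)) arr[10, 10, 10] <- 1L
    mask <- seg_mask(arr)
    for (s in 1:5)
      expect_identical(count_boxes(mask, s),
                       naive_box_count(arr, s))
  }
})

test_that("boxcount_curve produces self-similar counts and drops the flat tail", {
  m3 <- make_phantom("menger", 3)
  cv <- boxcount_curve(m3, c(1L, 3L, 9L, 27L))
  expect_equal(cv$counts, c(8000, 400, 20, 1))
  cube <- make_phantom("cube", 64)
  cv2 <- boxcount_curve(cube, box_size_schedule(c(64, 64, 64), "pow2"))
  expect_equal(cv2$counts, (64 / cv2$sizes)^3)
  expect_true(all(diff(cv2$counts) <= 0))
  # N = 1 entries beyond the first are dropped
  tiny <- array(0L, c(40, 40, 40)); tiny[20:21, 20:21, 20:21] <- 1L
  cv3 <- boxcount_curve(seg_mask(tiny), c(1L, 2L, 4L, 8L, 16L))
  expect_equal(sum(cv3$counts == 1), 1)
})

test_that("fits recover exact dimensions on analytic phantoms", {
  m3 <- make_phantom("menger", 3)
  f <- fit_fractal_dimension(boxcount_curve(m3, c(1L, 3L, 9L, 27L)), "all")
  expect_equal(f$fd, log(20) / log(3), tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  slab <- make_phantom("slab", 64)
  fs <- fit_fractal_dimension(
    boxcount_curve(slab, box_size_schedule(c(64, 64, 64), "pow2")), "all")
  expect_equal(fs$fd, 2, tolerance = 1e-9)
  # degenerate curve: all counts equal -> flagged
  cv <- structure(list(sizes = c(1L, 2L, 4L), counts = c(5, 5, 5),
                       anchor = "bbox"), class = "box_count_curve")
  fd_deg <- fit_fractal_dimension(cv, "all")
  expect_true(fd_deg$flagged)
  expect_true(is.na(fd_deg$fd))
})

test_that("best_window picks the contiguous sub-range maximizing r2", {
  # two clean regimes: slope 3 at fine scales, then a corrupted tail
  sizes <- c(1L, 2L, 4L, 8L, 16L, 32L)
  counts <- c(8^6 / sizes[1:4]^3, 90, 70)
  cv <- structure(list(sizes = sizes, counts = counts, anchor = "bbox"),
                  class = "box_count_curve")
  f <- fit_fractal_dimension(cv, "best_window", min_points = 3)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$fd, 3, tolerance = 1e-9)
  expect_true(all(f$fit_sizes %in% c(1L, 2L, 4L, 8L)))
})

test_that("fd is translation invariant and stable under 2x upsampling", {
  base <- array(0L, c(40, 40, 40))
  set.seed(7)
  blob <- array(as.integer(stats::runif(12^3) < 0.6), c(12, 12, 12))
  base[3:14, 3:14, 3:14] <- blob
  shifted <- array(0L, c(40, 40, 40))
  shifted[21:32, 15:26, 9:20] <- blob
  sched <- c(1L, 2L, 4L)
  f1 <- fit_fractal_dimension(boxcount_curve(seg_mask(base), sched), "all")
  f2 <- fit_fractal_dimension(boxcount_curve(seg_mask(shifted), sched), "all")
  expect_identical(f1$fd, f2$fd)

  cube <- make_phantom("cube", 32)
  fd1 <- mask_fd(cube)
  big <- seg_mask(cube$data[rep(1:32, each = 2), rep(1:32, each = 2),
                            rep(1:32, each = 2)])
  expect_lt(abs(mask_fd(big) - fd1), 0.02)
})

test_that("phantom dimension ordering holds", {
  fd_line <- mask_fd(make_phantom("line", 64), shape = rep(64L, 3))
  fd_slab <- mask_fd(make_phantom("slab", 64), shape = rep(64L, 3))
  fd_menger <- mask_fd(make_phantom("menger", 3), "ternary")
  fd_cube <- mask_fd(make_phantom("cube", 64))
  expect_true(fd_line < fd_slab && fd_slab < fd_menger &&
                fd_menger < fd_cube)
  expect_lt(abs(fd_line - 1), 0.1)
  expect_lt(abs(fd_slab - 2), 0.1)
  expect_lt(abs(fd_menger - log(20) / log(3)), 0.1)
  expect_lt(abs(fd_cube - 3), 0.1)
})

test_that("local_fd_map geometry and fd_max follow their definitions", {
  cube <- make_phantom("cube", 64)
  lm_ <- local_fd_map(cube, window = 32, stride = 16)
  expect_identical(dim(lm_$map), c(3L, 3L, 3L))
  expect_true(all(abs(lm_$map - 3) < 0.1))
  expect_equal(lm_$fd_max, max(lm_$map, na.rm = TRUE))
  expect_error(local_fd_map(cube, window = 128), "exceeds")
  empty_corner <- array(0L, c(48, 48, 48))
  empty_corner[1:8, 1:8, 1:8] <- 1L
  lm2 <- local_fd_map(seg_mask(empty_corner), window = 16, stride = 16)
  expect_true(is.na(lm2$map[3, 3, 3]))  # windows without foreground invalid
})

test_that("compute_fd runs the full path deterministically", {
  dir <- tempfile("fdrun"); dir.create(dir)
  m3 <- make_phantom("menger", 3)
  mp <- file.path(dir, "mask.nii.gz")
  write_nifti(m3, mp)
  cfg <- fd_config(schedule = "ternary", crop_margin = 0L)
  res1 <- compute_fd(NULL, mp, cfg, patient_id = "M3")
  expect_equal(res1$row$fd, log(20) / log(3), tolerance = 0.02)
  expect_equal(res1$row$voxels, 8000)
  res2 <- compute_fd(NULL, mp, cfg, patient_id = "M3")
  expect_identical(res1$row, res2$row)

  empty <- seg_mask(array(0L, c(8, 8, 8)))
  ep <- file.path(dir, "empty.nii")
  write_nifti(empty, ep)
  expect_error(compute_fd(NULL, ep, cfg), "empty.nii")
  unlink(dir, recursive = TRUE)
})

test_that("grayscale variant runs and stays in a sane range", {
  sph <- make_phantom("sphere", 12)
  set.seed(5)
  hu <- array(stats::rnorm(length(sph$data), 100, 40), dim(sph$data))
  q <- quantize_intensity(ct_volume(hu), c(-200, 400))
  f <- fd_grayscale(q, sph)
  expect_false(f$flagged)
  expect_gt(f$fd, 2)
  expect_lt(f$fd, 3.2)
})
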