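# Cohort simulator: calibration machinery and generated-table contracts.

test_that("truncated-normal calibration matches requested moments", {
  # both moments reachable for the MVI- class target
  cal <- calibrate_truncnorm(2.78, 0.19, c(2, 3))
  mo <- tumorfd:::tn_moments(cal$mu, cal$sigma, 2, 3)
  expect_equal(mo$mean, 2.78, tolerance = 1e-8)
  expect_equal(mo$sd, 0.19, tolerance = 0.19 * 0.05)
  expect_true(cal$sd_matched)
  # near the upper bound the SD target is unattainable; mean still exact
  cal2 <- calibrate_truncnorm(2.95, 0.10, c(2, 3))
  mo2 <- tumorfd:::tn_moments(cal2$mu, cal2$sigma, 2, 3)
  expect_equal(mo2$mean, 2.95, tolerance = 1e-8)
  expect_false(cal2$sd_matched)
  expect_lt(mo2$sd, 0.10)
  # inverse-CDF sampler agrees with the analytic moments
  u <- (seq_len(20000) - 0.5) / 20000
  x <- tumorfd:::tn_quantile(u, cal$mu, cal$sigma, 2, 3)
  expect_equal(mean(x), 2.78, tolerance = 1e-3)
  expect_equal(stats::sd(x), mo$sd, tolerance = 1e-2)
  expect_true(all(x >= 2 & x <= 3))
})

test_that("intercept bisection hits the target prevalence in expectation", {
  cfg <- sim_config()
  b0 <- calibrate_intercept(cfg, "label_conditional")
  cells <- tumorfd:::covariate_cells(cfg)
  expect_equal(sum(cells$p * stats::plogis(b0 + cells$lp)), 0.298,
               tolerance = 1e-9)
  b0c <- calibrate_intercept(cfg, "covariate")
  expect_lt(b0c, b0)  # FD term carries positive mass, intercept compensates
})

test_that("simulated cohorts respect support, seeds and counter-based streams", {
  cfg <- sim_config()
  tab <- simulate_cohort(cfg, n = 400, seed = 9)
  expect_identical(nrow(tab), 400L)
  expect_true(all(tab$fd >= 2 & tab$fd <= 3))
  expect_true(all(tab$rfs_months >= 0 & tab$os_months >= 0))
  expect_true(all(tab$rfs_event %in% 0:1 & tab$os_event %in% 0:1))
  expect_true(all(tab$mvi %in% 0:1))
  expect_true(all(tab$diameter_cm[tab$size_gt5 == 1] > 5))
  expect_true(all(tab$diameter_cm[tab$size_gt5 == 0] <= 5))
  expect_identical(simulate_cohort(cfg, n = 400, seed = 9), tab)
  # growing n leaves earlier patients untouched
  expect_equal(simulate_cohort(cfg, n = 150, seed = 9), tab[1:150, ],
               ignore_attr = TRUE)
  expect_false(identical(simulate_cohort(cfg, n = 400, seed = 10)$fd,
                         tab$fd))
})

test_that("class-conditional FD moments and prevalence calibrate at n = 10^4", {
  tab <- simulate_cohort(sim_config(), n = 10000, seed = 2)
  expect_lt(abs(mean(tab$mvi) - 0.298), 0.02)
  expect_lt(abs(mean(tab$fd[tab$mvi == 1]) - 2.95), 0.01)
  expect_lt(abs(mean(tab$fd[tab$mvi == 0]) - 2.78), 0.01)
  # MVI- class: empirical SD within 10% of the configured SD
  expect_lt(abs(stats::sd(tab$fd[tab$mvi == 0]) - 0.19) / 0.19, 0.10)
  # both classes: empirical SD within 10% of the calibrated analytic SD
  cal <- attr(tab, "fd_calibration")
  expect_lt(abs(stats::sd(tab$fd[tab$mvi == 1]) - cal$pos$sd) / cal$pos$sd,
            0.10)
  expect_lt(abs(stats::sd(tab$fd[tab$mvi == 0]) - cal$neg$sd) / cal$neg$sd,
            0.10)
  # covariate prevalences
  expect_lt(abs(mean(tab$afp_high) - 0.377), 0.02)
  expect_lt(abs(mean(tab$size_gt5) - 0.544), 0.02)
  expect_lt(abs(mean(tab$multiple_tumors) - 0.106), 0.02)
})

test_that("survival generator reproduces class medians without censoring", {
  cfg <- sim_config(censor_frac = 0)
  tab <- simulate_cohort(cfg, n = 10000, seed = 3)
  med <- function(cls, col) stats::median(tab[[col]][tab$mvi == cls])
  expect_lt(abs(med(1, "rfs_months") - 28) / 28, 0.15)
  expect_lt(abs(med(0, "rfs_months") - 43) / 43, 0.15)
  expect_lt(abs(med(1, "os_months") - 40) / 40, 0.15)
  expect_lt(abs(med(0, "os_months") - 58) / 58, 0.15)
  expect_true(all(tab$rfs_event == 1L))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(mvi_prevalence = 1.5), "prevalences")
  expect_error(sim_config(fd_sd = c(pos = -1, neg = 0.1)), "fd_sd")
  expect_error(sim_config(censor_frac = 1), "censor_frac")
  expect_error(sim_config(median_rfs = c(pos = -2, neg = 43)), "medians")
})

test_that("voxel cohort measures FD through the imaging path", {
  tab <- simulate_voxel_cohort(n = 40, seed = 7)
  expect_identical(nrow(tab), 40L)
  expect_false(any(is.na(tab$fd)))
  expect_true(all(tab$fd > 1.5 & tab$fd < 3.1))
  # the geometry signal: FD falls with roughness, rises with radius
  # (see ledger/vignette for why the roughness sign is negative)
  fit <- summary(stats::lm(fd ~ roughness + radius, data = tab))$coefficients
  expect_lt(fit["roughness", 1], 0)
  expect_lt(fit["roughness", 4], 0.01)
  expect_gt(fit["radius", 1], 0)
  expect_lt(fit["radius", 4], 0.01)
  # FD carries MVI class signal through geometry (direction as measured)
  expect_false(isTRUE(all.equal(mean(tab$fd[tab$mvi == 1]),
                                mean(tab$fd[tab$mvi == 0]))))
  expect_identical(simulate_voxel_cohort(n = 40, seed = 7), tab)
  expect_error(simulate_voxel_cohort(n = 600), "max_n")
})

test_that("voxel cohort writes readable NIfTI masks on request", {
  dir <- tempfile("masks")
  tab <- simulate_voxel_cohort(n = 3, seed = 1, out_dir = dir)
  expect_true(all(file.exists(tab$mask_path)))
  m <- read_nifti_mask(tab$mask_path[1])
  expect_equal(sum(m$data), tab$voxels[1])
  unlink(dir, recursive = TRUE)
})
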