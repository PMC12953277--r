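# ROC/DeLong, calibration, decision curves, ICC, Kaplan-Meier, log-rank.

test_that("AUC equals brute-force pair counting, with ties", {
  set.seed(19)
  for (rep in 1:300) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    r <- roc_auc_delong(scores, labels)
    expect_equal(r$auc, brute_auc(scores, labels), tolerance = 1e-14)
  }
  r <- roc_auc_delong(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  r2 <- roc_auc_delong(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(r2$auc, 0)
  expect_error(roc_auc_delong(1:4, rep(1, 4)), "both classes")
})

test_that("AUC symmetry and CI sanity", {
  set.seed(23)
  scores <- stats::rnorm(60)
  labels <- rep(0:1, 30)
  a <- roc_auc_delong(scores, labels)
  b <- roc_auc_delong(-scores, labels)
  expect_equal(a$auc + b$auc, 1, tolerance = 1e-12)
  expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])
  expect_true(all(a$ci >= 0 & a$ci <= 1))
})

test_that("paired DeLong test: identity, antisymmetry", {
  set.seed(29)
  labels <- rep(0:1, each = 40)
  sa <- stats::rnorm(80) + labels
  sb <- stats::rnorm(80) + labels
  same <- delong_paired_test(sa, sa, labels)
  expect_true(same$flagged)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- delong_paired_test(sa, sb, labels)
  ba <- delong_paired_test(sb, sa, labels)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("performance_at_cutoff reproduces 2x2 arithmetic", {
  # TP=8 FN=2 TN=15 FP=5
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.2, 15), rep(0.8, 5))
  labels <- c(rep(1, 10), rep(0, 20))
  perf <- performance_at_cutoff(scores, labels, 0.5)
  expect_equal(unname(perf), c(0.8, 0.75, 23 / 30))
  expect_equal(unname(performance_at_cutoff(scores, labels, 2)),
               c(0, 1, 2 / 3))
  ok <- performance_at_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1), 5)
  expect_equal(unname(ok), c(1, 1, 1))
})

test_that("Hosmer-Lemeshow matches a hand-binned oracle", {
  # two explicit bins: low-risk 0.2, high-risk 0.7, 10 patients each
  probs <- c(rep(0.2, 10), rep(0.7, 10))
  labels <- c(rep(1, 3), rep(0, 7), rep(1, 6), rep(0, 4))
  hl <- hosmer_lemeshow(probs, labels, g = 2)
  chi_hand <- (3 - 2)^2 / 2 + (7 - 8)^2 / 8 +
    (6 - 7)^2 / 7 + (4 - 3)^2 / 3
  expect_equal(hl$chi2, chi_hand, tolerance = 1e-12)
  expect_identical(hl$df, 0L)  # 2 bins - 2

  # constant probabilities equal to the event rate: perfect calibration
  hl0 <- hosmer_lemeshow(rep(0.3, 20), c(rep(1, 6), rep(0, 14)))
  expect_equal(hl0$chi2, 0, tolerance = 1e-12)
  expect_error(hosmer_lemeshow(c(0, stats::runif(19)), rep(0:1, 10)),
               "strictly")
})

test_that("decision curve matches closed forms", {
  labels <- c(rep(1, 30), rep(0, 70))
  perfect <- decision_curve(labels * 0.98 + 0.01, labels,
                            thresholds = c(0.1, 0.3, 0.5, 0.9))
  expect_equal(perfect$nb_model, rep(0.3, 4), tolerance = 1e-12)
  expect_equal(perfect$nb_none, rep(0, 4))
  expect_equal(perfect$nb_all,
               0.3 - 0.7 * perfect$threshold / (1 - perfect$threshold),
               tolerance = 1e-12)
})

test_that("ICC(2,1): identity, rater shift, and null behavior", {
  set.seed(37)
  x <- stats::rnorm(30, mean = 2.8, sd = 0.15)
  same <- icc_agreement(cbind(x, x))
  expect_equal(same$icc, 1, tolerance = 1e-9)
  shifted <- icc_agreement(cbind(x, x + 0.1))
  expect_lt(shifted$icc, 1)
  # mean-squares oracle for the shifted case
  r <- cbind(x, x + 0.1); n <- 30; k <- 2
  rm_ <- rowMeans(r); cm_ <- colMeans(r); g <- mean(r)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm_ - g)^2) / (k - 1)
  mse <- sum((r - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + g)^2) /
    ((n - 1) * (k - 1))
  icc_hand <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(shifted$icc, icc_hand, tolerance = 1e-12)
  expect_true(shifted$ci[1] <= shifted$icc && shifted$icc <= shifted$ci[2])
  null <- icc_agreement(matrix(stats::rnorm(1000), ncol = 2))
  expect_lt(abs(null$icc), 0.1)
  expect_error(icc_agreement(matrix(1:6, ncol = 2)), ">= 5 subjects")
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  k <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$surv, c(2 / 3, 1 / 3, 0))
  # censored case 1+, 2, 3+, 4: S(2) = 2/3, S(4) = 0
  k2 <- km_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(km_surv_at(k2, 2), 2 / 3, tolerance = 1e-12)
  expect_equal(km_surv_at(k2, 4), 0)
  expect_equal(km_surv_at(k2, 1.5), 1)  # censoring does not drop the curve
  allc <- km_curve(c(5, 6, 7), c(0, 0, 0))
  expect_length(allc$time, 0)
  expect_true(is.na(allc$median))
  expect_error(km_curve(numeric(0), integer(0)), "empty")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(41)
  t <- round(stats::rexp(200, 0.1), 1)
  k <- km_curve(t, rep(1, 200))
  for (q in c(0.25, 0.5, 0.9)) {
    tt <- unname(stats::quantile(t, q, type = 1))
    expect_equal(km_surv_at(k, tt), mean(t > tt), tolerance = 1e-12)
  }
})

test_that("km_curve and logrank_test agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(43)
  t1 <- stats::rexp(80, log(2) / 28); e1 <- stats::rbinom(80, 1, 0.8)
  t2 <- stats::rexp(90, log(2) / 43); e2 <- stats::rbinom(90, 1, 0.8)
  k <- km_curve(t1, e1)
  sf <- survival::survfit(survival::Surv(t1, e1) ~ 1)
  ev <- sf$time[sf$n.event > 0]
  expect_equal(k$time, ev)
  expect_equal(km_surv_at(k, ev), sf$surv[sf$n.event > 0],
               tolerance = 1e-10)
  expect_equal(k$median,
               unname(summary(sf)$table["median"]), tolerance = 1e-10)
  lr <- logrank_test(t1, e1, t2, e2)
  sd_ <- survival::survdiff(
    survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, c(80, 90)))
  expect_equal(lr$chi2, sd_$chisq, tolerance = 1e-10)
  expect_equal(lr$observed, unname(sd_$obs), tolerance = 1e-10)
  expect_equal(lr$expected, unname(sd_$exp), tolerance = 1e-10)
})

test_that("log-rank: identical groups give chi2 = 0 and label swap invariance", {
  t <- c(3, 5, 8, 12, 12, 20); e <- c(1, 0, 1, 1, 0, 1)
  same <- logrank_test(t, e, t, e)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  set.seed(47)
  ta <- stats::rexp(40, 0.05); ea <- stats::rbinom(40, 1, 0.7)
  tb <- stats::rexp(50, 0.10); eb <- stats::rbinom(50, 1, 0.7)
  ab <- logrank_test(ta, ea, tb, eb)
  ba <- logrank_test(tb, eb, ta, ea)
  expect_equal(ab$chi2, ba$chi2, tolerance = 1e-12)
  none <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_true(none$flagged)
  expect_equal(none$p, 1)
})

test_that("hand worked log-rank instance matches the O-E accumulation", {
  # group A: events at 1, 3; group B: event at 2, censored at 4
  lr <- logrank_test(c(1, 3), c(1, 1), c(2, 4), c(1, 0))
  # risk sets: t=1: nA=2,nB=2,d=1 -> eA=.5, v=.25
  #            t=2: nA=1,nB=2,d=1 -> eA=1/3, v=2/9
  #            t=3: nA=1,nB=1,d=1 -> eA=.5, v=.25
  oA <- 2; eA <- 0.5 + 1 / 3 + 0.5; v <- 0.25 + 2 / 9 + 0.25
  expect_equal(lr$chi2, (oA - eA)^2 / v, tolerance = 1e-12)
})
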