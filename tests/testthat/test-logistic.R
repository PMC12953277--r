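# Logistic model building, screening, VIF, scoring, Youden cut-off.

make_2x2 <- function(a, b, c_, d) {
  # a: exposed cases, b: exposed controls, c_: unexposed cases, d: unexposed
  data.frame(x = c(rep(1, a + b), rep(0, c_ + d)),
             mvi = c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d)))
}

test_that("univariable OR equals the cross-product ratio on 2x2 data", {
  f <- fit_univariable(make_2x2(20, 10, 10, 20), "x")
  expect_equal(unname(f$or["x"]), 4, tolerance = 1e-6)
  expect_true(f$converged)
  expect_true(f$ci_low["x"] < 4 && f$ci_high["x"] > 4)
  # symmetric counts: no association, OR = 1
  f0 <- fit_univariable(make_2x2(15, 15, 15, 15), "x")
  expect_equal(unname(f0$or["x"]), 1, tolerance = 1e-6)
  expect_gt(f0$p[["x"]], 0.99)
})

test_that("perfect separation flags non-convergence; constants error", {
  sep <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                    mvi = c(rep(0, 20), rep(1, 20)))
  f <- fit_univariable(sep, "x")
  expect_false(f$converged)
  expect_error(fit_univariable(data.frame(x = rep(1, 40),
                                          mvi = rep(0:1, 20)), "x"),
               "constant")
  expect_error(fit_univariable(data.frame(x = 1:10, mvi = rep(1, 10)), "x"),
               "single class")
})

test_that("select_variables applies the strict p < alpha rule in order", {
  fake_fit <- function(v, p, conv = TRUE) {
    structure(list(variables = v, p = stats::setNames(p, v),
                   converged = conv), class = "logistic_fit")
  }
  fits <- list(fake_fit("a", 0.001), fake_fit("b", 0.04),
               fake_fit("c", 0.06), fake_fit("d", 0.05))
  expect_identical(select_variables(fits), c("a", "b"))  # 0.05 excluded
  expect_warning(sel <- select_variables(list(fake_fit("a", 0.2))),
                 "no variable")
  expect_length(sel, 0)
  expect_warning(select_variables(list(fake_fit("x", 0.01, conv = FALSE),
                                       fake_fit("y", 0.01))),
                 "non-converged")
  # idempotent / order-stable
  expect_identical(select_variables(fits), select_variables(rev(fits))[2:1])
})

test_that("multivariable fit matches univariable for one predictor and recovers truth", {
  tab <- simulate_cohort(sim_config(), n = 800, seed = 5)
  fu <- fit_univariable(tab, "fd")
  fm <- fit_multivariable(tab, "fd")
  expect_equal(fm$coef, fu$coef, tolerance = 1e-8)
  expect_equal(fm$intercept, fu$intercept, tolerance = 1e-8)

  # duplicated column is exact collinearity
  tab$fd2 <- tab$fd
  expect_error(fit_multivariable(tab, c("fd", "fd2")), "rank-deficient")
})

test_that("parameter recovery on the forward (covariate-mode) generator", {
  tab <- simulate_cohort(sim_config(), n = 5000, seed = 11,
                         mode = "covariate")
  fit <- fit_multivariable(tab, c("afp_high", "size_gt5",
                                  "multiple_tumors", "fd"))
  truth <- c(afp_high = log(2.19), size_gt5 = log(4.16),
             multiple_tumors = log(3.87), fd = log(62.21))
  for (v in names(truth)) {
    expect_lt(abs(fit$coef[[v]] - truth[[v]]), 2 * fit$se[[v]])
  }
  # optimality: fitted likelihood >= likelihood at the generating truth
  X <- as.matrix(tab[, names(truth)])
  b0 <- attr(tab, "intercept") - log(62.21) * 2.8  # uncentered intercept
  eta <- b0 + X %*% truth
  ll_truth <- sum(tab$mvi * eta - log1p(exp(eta)))
  expect_gte(fit$loglik, ll_truth)
})

test_that("VIF matches its definition and flags collinearity", {
  n <- 64
  x1 <- rep(c(1, -1), n / 2)
  x2 <- rep(c(1, 1, -1, -1), n / 4)
  x3 <- rep(c(1, 1, 1, 1, -1, -1, -1, -1), n / 8)  # mutually orthogonal
  tab <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  expect_equal(unname(compute_vif(tab, c("x1", "x2", "x3"))), rep(1, 3),
               tolerance = 1e-6)
  set.seed(31)
  a <- stats::rnorm(200); b <- a + stats::rnorm(200, sd = 0.5)
  r2 <- summary(stats::lm(b ~ a))$r.squared
  v <- compute_vif(data.frame(a = a, b = b), c("a", "b"))
  expect_equal(unname(v["b"]), 1 / (1 - r2), tolerance = 1e-8)
  tab$x1b <- tab$x1
  expect_true(is.infinite(compute_vif(tab, c("x1", "x1b"))[1]))
})

test_that("predict_risk computes the linear predictor and probability", {
  tab <- simulate_cohort(sim_config(), n = 500, seed = 13)
  fit <- fit_multivariable(tab, c("afp_high", "fd"))
  sc <- predict_risk(fit, tab)
  expect_equal(sc$probability, stats::plogis(sc$linear_predictor))
  i <- 17
  eta_hand <- fit$intercept + fit$coef[["afp_high"]] * tab$afp_high[i] +
    fit$coef[["fd"]] * tab$fd[i]
  expect_equal(sc$linear_predictor[i], eta_hand, tolerance = 1e-10)
  zero <- tab[3, ]; zero$afp_high <- 0; zero$fd <- 0
  expect_equal(predict_risk(fit, zero)$probability,
               stats::plogis(fit$intercept))
  expect_error(predict_risk(fit, tab[, "mvi", drop = FALSE]), "missing")
})

test_that("youden_cutoff equals exhaustive search on random instances", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::runif(n), sample(1:3, 1))  # force ties
    res <- youden_cutoff(scores, labels)
    expect_equal(res$j, brute_youden(scores, labels), tolerance = 1e-12)
    expect_equal(res$j, res$sensitivity + res$specificity - 1,
                 tolerance = 1e-12)
  }
  sep <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(sep$j, 1)
  expect_true(sep$threshold > 0.2 && sep$threshold <= 0.8)
  flat <- youden_cutoff(rep(0.5, 10), rep(0:1, 5))
  expect_equal(flat$j, 0)
  expect_error(youden_cutoff(1:5, rep(1, 5)), "both classes")
})
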