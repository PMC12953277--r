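# Logistic model building: univariable screen, multivariable combined model,
# collinearity check, risk scoring, Youden cut-off.

#' Fit a univariable logistic regression of MVI on one predictor
#'
#' Maximum-likelihood logistic fit (IRLS via `stats::glm`, tolerance 1e-8,
#' up to 100 iterations) with Wald standard errors, odds ratios with 95%
#' confidence intervals, and Wald p-values. Perfect separation is reported
#' through the `converged` flag (diverging coefficients), not an error.
#'
#' @param table Cohort `data.frame` (e.g. from [simulate_cohort()]).
#' @param variable Name of the predictor column.
#' @param outcome Name of the binary outcome column (default `"mvi"`).
#' @return A `logistic_fit`: list with `variables`, `coef`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p`, `intercept`, `converged`, `n_used`,
#'   `loglik`, `model`.
#' @export
fit_univariable <- function(table, variable, outcome = "mvi") {
  fit_logistic(table, variable, outcome)
}

#' Fit a multivariable logistic regression
#'
#' Joint maximum-likelihood fit of the outcome on several predictors with
#' per-variable odds ratios, Wald CIs and p-values. Exact collinearity is an
#' error naming the offending columns.
#'
#' @param table Cohort `data.frame`.
#' @param variables Character vector of predictor column names (>= 1).
#' @param outcome Name of the binary outcome column (default `"mvi"`).
#' @return A `logistic_fit` (see [fit_univariable()]).
#' @export
fit_multivariable <- function(table, variables, outcome = "mvi") {
  fit_logistic(table, variables, outcome)
}

fit_logistic <- function(table, variables, outcome = "mvi") {
  if (length(variables) < 1L) stop("need at least one predictor")
  missing_cols <- setdiff(c(variables, outcome), names(table))
  if (length(missing_cols) > 0L)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  y <- table[[outcome]]
  if (length(unique(y)) < 2L)
    stop("outcome '", outcome, "' has a single class")
  X <- as.matrix(table[, variables, drop = FALSE])
  storage.mode(X) <- "double"
  const <- apply(X, 2, function(col) stats::var(col) == 0)
  if (any(const))
    stop("constant predictor(s): ",
         paste(variables[const], collapse = ", "))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    drop_idx <- setdiff(seq_len(ncol(X) + 1L), qrX$pivot[seq_len(qrX$rank)])
    stop("rank-deficient design; offending column(s): ",
         paste(variables[drop_idx - 1L], collapse = ", "))
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~",
                                 paste(sprintf("`%s`", variables),
                                       collapse = " + ")))
  g <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(),
               data = df,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  sm <- suppressWarnings(summary(g))
  co <- sm$coefficients
  beta <- co[-1, 1]
  se <- co[-1, 2]
  # separation / non-convergence: IRLS gave up, or coefficients diverged.
  # Separation manifests as coefficients drifting to +/- 30+ with standard
  # errors in the thousands; genuine steep effects (e.g. FD on its
  # 0.2-wide class gap) keep finite SEs.
  converged <- g$converged && all(abs(beta) < 40) && all(se < 100)
  z <- 1.959963984540054
  structure(list(
    variables = variables,
    coef = stats::setNames(beta, variables),
    se = stats::setNames(se, variables),
    or = stats::setNames(exp(beta), variables),
    ci_low = stats::setNames(exp(beta - z * se), variables),
    ci_high = stats::setNames(exp(beta + z * se), variables),
    p = stats::setNames(co[-1, 4], variables),
    intercept = unname(co[1, 1]),
    converged = converged,
    n_used = stats::nobs(g),
    loglik = as.numeric(stats::logLik(g)),
    outcome = outcome,
    model = g),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %s ~ %s (n = %d%s)\n", x$outcome,
              paste(x$variables, collapse = " + "), x$n_used,
              if (x$converged) "" else ", NOT CONVERGED"))
  tab <- data.frame(OR = sprintf("%.2f", x$or),
                    `95% CI` = sprintf("%.2f-%.2f", x$ci_low, x$ci_high),
                    p = format.pval(x$p, digits = 3),
                    check.names = FALSE, row.names = x$variables)
  print(tab)
  invisible(x)
}

#' Univariable screen at a significance threshold
#'
#' Keeps variables whose univariable Wald p-value is strictly below `alpha`
#' (the conventional p < 0.05 screen feeding the multivariable model),
#' preserving input order. Non-converged fits are excluded with a warning.
#'
#' @param fits List of `logistic_fit` objects from [fit_univariable()].
#' @param alpha Screening threshold (default 0.05; strict inequality).
#' @return Character vector of selected variable names (possibly empty,
#'   with a warning).
#' @export
select_variables <- function(fits, alpha = 0.05) {
  keep <- character(0)
  for (f in fits) {
    stopifnot(inherits(f, "logistic_fit"))
    if (!f$converged) {
      warning("excluding non-converged fit for ",
              paste(f$variables, collapse = "+"))
      next
    }
    if (f$p[[1]] < alpha) keep <- c(keep, f$variables[1])
  }
  if (length(keep) == 0L)
    warning("no variable passed the p < ", alpha, " screen")
  keep
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the least-squares regression of predictor
#' `j` on the remaining predictors. Exact collinearity is reported as `Inf`
#' rather than an error.
#'
#' @param table Cohort `data.frame`.
#' @param variables Character vector of >= 2 predictor names.
#' @return Named numeric vector of VIFs.
#' @export
compute_vif <- function(table, variables) {
  if (length(variables) < 2L) stop("VIF needs >= 2 variables")
  X <- as.matrix(table[, variables, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(apply(X, 2, stats::var) == 0))
    stop("constant predictor among: ", paste(variables, collapse = ", "))
  vapply(seq_along(variables), function(j) {
    yj <- X[, j]
    Xj <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Xj, yj)
    ssr <- sum(fit$residuals^2)
    sst <- sum((yj - mean(yj))^2)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) -> v
  stats::setNames(v, variables)
}

#' Per-patient risk scores from a fitted model
#'
#' Linear predictor and logistic-transformed probability for each row of a
#' table containing the model's variables.
#'
#' @param fit A converged `logistic_fit`.
#' @param table `data.frame` with all model variables.
#' @return `data.frame` with columns `linear_predictor`, `probability`.
#' @export
predict_risk <- function(fit, table) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged)
    stop("model did not converge; refusing to score")
  missing_cols <- setdiff(fit$variables, names(table))
  if (length(missing_cols) > 0L)
    stop("missing model variable(s): ",
         paste(missing_cols, collapse = ", "))
  X <- as.matrix(table[, fit$variables, drop = FALSE])
  storage.mode(X) <- "double"
  eta <- as.vector(fit$intercept + X %*% fit$coef)
  data.frame(linear_predictor = eta, probability = stats::plogis(eta))
}

#' Youden-optimal cut-off
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over all candidate
#' thresholds (midpoints between adjacent distinct scores, plus sentinels
#' below the minimum and above the maximum). Classification rule:
#' `score >= threshold` is called positive. Ties in J are broken toward the
#' lower threshold.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return A `cutoff_result`: list with `threshold`, `j`, `sensitivity`,
#'   `specificity`.
#' @export
youden_cutoff <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2 else numeric(0)
  cand <- c(s[1] - 1, cand, s[length(s)] + 1)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  best <- NULL
  for (thr in cand) {
    pred <- scores >= thr
    sens <- sum(pred & labels == 1L) / n_pos
    spec <- sum(!pred & labels == 0L) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(threshold = thr, j = j, sensitivity = sens,
                   specificity = spec)
    }
  }
  structure(best, class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "<cutoff_result> threshold = %.4f, J = %.3f (sens %.3f, spec %.3f)\n",
    x$threshold, x$j, x$sensitivity, x$specificity))
  invisible(x)
}
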