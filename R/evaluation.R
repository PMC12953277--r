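# Discrimination, calibration, clinical utility, reader agreement, survival.

# Midranks (average ranks for ties), the building block of the DeLong
# structural components.
midranks <- function(x) rank(x, ties.method = "average")

delong_components <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L) stop("both classes must be present")
  r_all <- midranks(c(pos, neg))
  r_pos <- midranks(pos)
  r_neg <- midranks(neg)
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong variance and confidence interval
#'
#' Area under the ROC curve via the Mann-Whitney estimator (ties receive
#' half credit), its variance from the DeLong structural components, and a
#' Wald 95% CI truncated to \[0, 1\].
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels Binary labels (0/1), both classes present.
#' @param conf_level Confidence level (default 0.95).
#' @return A `roc_result`: list with `auc`, `var`, `ci`, `n_pos`, `n_neg`.
#' @export
roc_auc_delong <- function(scores, labels, conf_level = 0.95) {
  d <- delong_components(scores, labels)
  v <- stats::var(d$v10) / d$m + stats::var(d$v01) / d$n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(d$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  structure(list(auc = d$auc, var = v, ci = ci,
                 n_pos = d$m, n_neg = d$n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (95%% CI %.3f-%.3f; %d+/%d-)\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong paired test for two correlated AUCs
#'
#' Tests the AUC difference of two score vectors computed on the same
#' patients, using the covariance of the DeLong structural components.
#' Zero variance of the difference (e.g. identical scores) yields `z = 0`,
#' `p = 1` with `flagged = TRUE`.
#'
#' @param scores_a,scores_b Score vectors on the same patients.
#' @param labels Binary labels (0/1).
#' @return List with `auc_a`, `auc_b`, `z`, `p`, `flagged`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("score vectors and labels must have equal length")
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  v10 <- cbind(da$v10, db$v10)
  v01 <- cbind(da$v01, db$v01)
  s10 <- stats::cov(v10)
  s01 <- stats::cov(v01)
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / da$m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / da$n
  if (!is.finite(vd) || vd < 1e-16) {
    return(list(auc_a = da$auc, auc_b = db$auc, z = 0, p = 1,
                flagged = TRUE))
  }
  z <- (da$auc - db$auc) / sqrt(vd)
  list(auc_a = da$auc, auc_b = db$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), flagged = FALSE)
}

#' Sensitivity, specificity and accuracy at a cut-off
#'
#' From the 2x2 table at the rule `score >= cutoff` = positive.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), both classes present.
#' @param cutoff Decision threshold.
#' @return Named numeric vector `(sensitivity, specificity, accuracy)`.
#' @export
performance_at_cutoff <- function(scores, labels, cutoff) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1L)
  fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L)
  fp <- sum(pred & labels == 0L)
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(labels))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups patients into `g` bins by sample quantiles of predicted risk (tied
#' quantiles are merged, so heavy ties give fewer bins), sums
#' `(O - E)^2 / E` over the event and non-event cells of every bin, and
#' refers the statistic to a chi-squared distribution with `bins - 2`
#' degrees of freedom.
#'
#' @param probs Predicted probabilities in (0, 1).
#' @param labels Binary outcomes (0/1).
#' @param g Number of quantile groups (default 10).
#' @return List with `chi2`, `df`, `p` (`NA` with `flagged = TRUE` when
#'   fewer than 3 distinct bins exist), and the per-bin table.
#' @export
hosmer_lemeshow <- function(probs, labels, g = 10L) {
  labels <- as.integer(labels)
  n <- length(probs)
  if (n < g) stop("need at least g observations")
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie strictly in (0, 1)")
  breaks <- unique(stats::quantile(probs, seq(0, 1, length.out = g + 1),
                                   names = FALSE))
  if (length(breaks) < 2L) {
    # constant predictions: one bin, chi2 = (O-E)^2/E there, df undefined
    e1 <- sum(probs); o1 <- sum(labels)
    chi2 <- (o1 - e1)^2 / e1 + ((n - o1) - (n - e1))^2 / (n - e1)
    return(list(chi2 = chi2, df = NA_integer_, p = NA_real_,
                flagged = TRUE, table = NULL))
  }
  bin <- cut(probs, breaks, include.lowest = TRUE)
  o1 <- tapply(labels, bin, sum)
  e1 <- tapply(probs, bin, sum)
  nb <- tapply(probs, bin, length)
  keep <- !is.na(nb) & nb > 0
  o1 <- o1[keep]; e1 <- e1[keep]; nb <- nb[keep]
  e0 <- nb - e1
  if (any(e1 <= 0) || any(e0 <= 0))
    stop("a bin has zero expected count; use a smaller g")
  chi2 <- sum((o1 - e1)^2 / e1 + ((nb - o1) - e0)^2 / e0)
  df <- length(nb) - 2L
  p <- if (df >= 1L) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  list(chi2 = chi2, df = df, p = p, flagged = df < 1L,
       table = data.frame(n = as.vector(nb), observed = as.vector(o1),
                          expected = as.vector(e1)))
}

#' Decision curve analysis
#'
#' Net benefit of acting on `probs >= pt` across threshold probabilities:
#' `NB(pt) = TP/n - FP/n * pt / (1 - pt)`, alongside the treat-all and
#' treat-none strategies.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary outcomes (0/1).
#' @param thresholds Threshold probabilities in (0, 1).
#' @return `data.frame` with columns `threshold`, `nb_model`, `nb_all`,
#'   `nb_none`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  labels <- as.integer(labels)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly in (0, 1)")
  n <- length(labels)
  prev <- mean(labels)
  rows <- lapply(thresholds, function(pt) {
    act <- probs >= pt
    tp <- sum(act & labels == 1L) / n
    fp <- sum(act & labels == 0L) / n
    w <- pt / (1 - pt)
    data.frame(threshold = pt,
               nb_model = tp - fp * w,
               nb_all = prev - (1 - prev) * w,
               nb_none = 0)
  })
  do.call(rbind, rows)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater — the form
#' appropriate when each of several readers measures every subject once and
#' systematic reader offsets should count against agreement. The confidence
#' interval uses the F-distribution formulation with Satterthwaite degrees
#' of freedom.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (n >= 5 rows, k >= 2 columns, no missing cells).
#' @param conf_level Confidence level (default 0.95).
#' @return An `icc_result`: list with `icc`, `ci`, `model`, `flagged`.
#' @export
icc_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("missing cells are not supported")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L || k < 2L) stop("need >= 5 subjects and >= 2 raters")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings)
  colm <- colMeans(ratings)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  mse <- sum((ratings - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2) / ((n - 1) * (k - 1))
  flagged <- msr < 1e-12
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  structure(list(icc = icc, ci = c(lower, upper),
                 model = "two-way random, absolute agreement, single rater",
                 ms = c(msr = msr, msc = msc, mse = mse),
                 flagged = flagged),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.3f (95%% CI %.3f-%.3f)%s\n",
              x$icc, x$ci[1], x$ci[2],
              if (x$flagged) " [flagged: no between-subject variance]" else ""))
  invisible(x)
}

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimate of the survival function with numbers at risk,
#' and the median/IQR read off as the first times the curve drops to
#' <= 0.5 / 0.75 / 0.25 (flagged `NA` when the curve never crosses).
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A `survival_curve`: list with `time`, `n_risk`, `n_event`,
#'   `surv` (aligned vectors over distinct event times), `median`, `q25`,
#'   `q75`, `n`.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  if (any(times < 0)) stop("times must be >= 0")
  events <- as.integer(events)
  if (!all(events %in% c(0L, 1L))) stop("events must be 0/1")
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  et <- unique(times[events == 1L])
  n <- length(times)
  surv <- numeric(length(et))
  n_risk <- integer(length(et))
  n_event <- integer(length(et))
  s <- 1
  for (i in seq_along(et)) {
    at_risk <- sum(times >= et[i])
    d <- sum(times == et[i] & events == 1L)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
    n_risk[i] <- at_risk
    n_event[i] <- d
  }
  qtime <- function(level) {
    idx <- which(surv <= level + 1e-12)
    if (length(idx) == 0L) NA_real_ else et[idx[1]]
  }
  structure(list(time = et, n_risk = n_risk, n_event = n_event,
                 surv = surv, median = qtime(0.5), q25 = qtime(0.75),
                 q75 = qtime(0.25), n = n),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf(
    "<survival_curve> n = %d, %d event times; median %s [IQR %s-%s]\n",
    x$n, length(x$time),
    ifelse(is.na(x$median), "not reached", format(x$median, digits = 3)),
    ifelse(is.na(x$q25), "NR", format(x$q25, digits = 3)),
    ifelse(is.na(x$q75), "NR", format(x$q75, digits = 3))))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Step-function lookup: `S(t)` = product-limit estimate at the latest event
#' time `<= t` (1 before the first event).
#'
#' @param curve A `survival_curve` from [km_curve()].
#' @param t Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(ti) {
    idx <- which(curve$time <= ti + 1e-12)
    if (length(idx) == 0L) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-squared from observed-minus-expected events
#' accumulated over the pooled risk sets at every distinct event time, with
#' the hypergeometric variance.
#'
#' @param times_a,events_a Follow-up times and event flags, group A.
#' @param times_b,events_b Follow-up times and event flags, group B.
#' @return List with `chi2`, `p`, `observed` (length-2), `expected`
#'   (length-2), `flagged` (`TRUE` when no events at all, p forced to 1).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must be non-empty")
  times <- c(times_a, times_b)
  events <- as.integer(c(events_a, events_b))
  group <- c(rep(1L, length(times_a)), rep(2L, length(times_b)))
  et <- sort(unique(times[events == 1L]))
  if (length(et) == 0L)
    return(list(chi2 = 0, p = 1,
                observed = c(0, 0), expected = c(0, 0), flagged = TRUE))
  o1 <- 0; e1 <- 0; vsum <- 0; o2 <- 0; e2 <- 0
  for (t in et) {
    at <- times >= t
    n_t <- sum(at)
    n1 <- sum(at & group == 1L)
    n2 <- n_t - n1
    d <- sum(times == t & events == 1L)
    d1 <- sum(times == t & events == 1L & group == 1L)
    o1 <- o1 + d1
    o2 <- o2 + (d - d1)
    e1 <- e1 + d * n1 / n_t
    e2 <- e2 + d * n2 / n_t
    if (n_t > 1)
      vsum <- vsum + d * (n1 / n_t) * (n2 / n_t) * (n_t - d) / (n_t - 1)
  }
  if (vsum <= 0)
    return(list(chi2 = 0, p = 1, observed = c(o1, o2),
                expected = c(e1, e2), flagged = TRUE))
  chi2 <- (o1 - e1)^2 / vsum
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       observed = c(o1, o2), expected = c(e1, e2), flagged = FALSE)
}
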