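# Study orchestration: simulate or ingest, model, evaluate, stratify,
# and emit one reproducible report bundle.

# Tiny FNV-1a hash over a canonical JSON rendering; used to fingerprint
# configs in output artifacts (no hashing package in the dependency set).
config_hash <- function(x) {
  bytes <- charToRaw(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                      force = TRUE))
  # FNV-1a in doubles: R's bitwXor is 31-bit, so XOR only the low byte
  # (the data byte never exceeds 255) and multiply in 16-bit halves to
  # stay exact under 2^53.
  h <- 2166136261
  m <- 16777619
  for (b in as.integer(bytes)) {
    h <- (h - h %% 256) + bitwXor(h %% 256, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Default run configuration
#'
#' @param mode `"simulate_table"` (label-conditional cohort),
#'   `"simulate_voxel"` (voxel-level tumors), or `"real_data"` (read a
#'   cohort CSV with the [simulate_cohort()] column contract from
#'   `cohort_csv`).
#' @param sim A [sim_config()].
#' @param n_train,n_test Training/test cohort sizes in simulation modes;
#'   the two cohorts use seeds derived from the master seed, mirroring a
#'   chronological split into independent sets.
#' @param seed Master seed.
#' @param cohort_csv Path to a cohort CSV (`real_data` mode). The table is
#'   split chronologically (first `n_train` rows train, rest test).
#' @param alpha Univariable screening threshold.
#' @param hl_groups Hosmer-Lemeshow bins.
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("simulate_table", "simulate_voxel",
                                "real_data"),
                       sim = sim_config(), n_train = 406L, n_test = 170L,
                       seed = 1L, cohort_csv = NULL, alpha = 0.05,
                       hl_groups = 10L, out_dir = NULL) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, sim = sim, n_train = as.integer(n_train),
              n_test = as.integer(n_test), seed = as.integer(seed),
              cohort_csv = cohort_csv, alpha = alpha,
              hl_groups = as.integer(hl_groups), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Validate and normalize a run configuration file
#'
#' Reads a JSON configuration, fills defaults from [run_config()] /
#' [sim_config()], rejects unknown keys and out-of-range values, and (when
#' an output directory is configured) echoes the normalized configuration
#' next to the outputs. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a JSON configuration file.
#' @return A normalized `run_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nchar(trimws(txt)) == 0L) list()
          else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!is.list(user)) stop("config must be a JSON object")
  base <- run_config()
  known_top <- setdiff(names(base), character(0))
  unknown <- setdiff(names(user), known_top)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  sim_user <- user$sim
  user$sim <- NULL
  for (k in names(user)) {
    if (!is.null(user[[k]])) base[[k]] <- user[[k]]  # JSON null = default
  }
  if (!is.null(sim_user)) {
    sim_args <- unclass(sim_config())
    unknown_sim <- setdiff(names(sim_user), names(sim_args))
    if (length(unknown_sim) > 0L)
      stop("unknown sim config key(s): ",
           paste(unknown_sim, collapse = ", "))
    for (k in names(sim_user)) {
      v <- sim_user[[k]]
      tmpl <- sim_args[[k]]
      if (!is.null(names(tmpl)) && length(v) == length(tmpl) &&
          is.null(names(v)))
        names(v) <- names(tmpl)
      sim_args[[k]] <- v
    }
    base$sim <- do.call(sim_config, sim_args)
  }
  base$mode <- match.arg(base$mode,
                         c("simulate_table", "simulate_voxel", "real_data"))
  if (base$n_train < 20L || base$n_test < 10L)
    stop("n_train/n_test too small for model fitting")
  if (base$alpha <= 0 || base$alpha >= 1)
    stop("alpha out of range (0, 1)")
  if (base$mode == "real_data" &&
      (is.null(base$cohort_csv) || !file.exists(base$cohort_csv)))
    stop("real_data mode requires an existing 'cohort_csv'")
  validate_sim_config(base$sim)
  class(base) <- "run_config"
  if (!is.null(base$out_dir)) {
    if (!dir.exists(base$out_dir))
      dir.create(base$out_dir, recursive = TRUE)
    save_config(base, file.path(base$out_dir, "config_normalized.json"))
  }
  base
}

#' Write a run configuration as JSON
#'
#' Round-trips through [validate_config()]: `validate_config(save_config(x))`
#' reproduces `x`.
#'
#' @param cfg A `run_config`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$sim <- unclass(out$sim)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

stage_log <- function(log, stage, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(...))
  message(line)
  c(log, line)
}

#' Run the full study replica
#'
#' End-to-end pipeline: obtain training and test cohorts (simulated or
#' read), screen candidate predictors univariably at `alpha`, fit the
#' clinical, FD-only and combined logistic models, evaluate discrimination
#' (AUC with DeLong CIs, paired DeLong combined vs clinical), calibration
#' (Hosmer-Lemeshow), clinical utility (decision curve), pick the Youden
#' cut-off on training scores, stratify the test cohort into high/low
#' predicted-MVI risk, and compare RFS/OS between strata by Kaplan-Meier
#' and log-rank. All randomness derives from the master seed; the report
#' embeds the seed and a config hash so equal configurations give equal
#' bundles.
#'
#' @param cfg A `run_config` from [run_config()] / [validate_config()].
#' @return A `study_report` list (metrics, models, tables, log). When
#'   `cfg$out_dir` is set, writes `metrics.json`, `cohort_train.csv`,
#'   `cohort_test.csv`, `scores_test.csv`, `decision_curve.csv`,
#'   `km_rfs.csv`, `km_os.csv` and `run_log.txt` there.
#' @export
run_study <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  log <- character(0)
  hash <- config_hash(list(mode = cfg$mode, sim = unclass(cfg$sim),
                           n_train = cfg$n_train, n_test = cfg$n_test,
                           seed = cfg$seed, alpha = cfg$alpha,
                           hl_groups = cfg$hl_groups))
  seed_train <- derive_seed(cfg$seed, 1L, 101L)
  seed_test <- derive_seed(cfg$seed, 2L, 202L)

  get_cohort <- switch(cfg$mode,
    simulate_table = function(n, sd) simulate_cohort(cfg$sim, n, sd),
    simulate_voxel = function(n, sd) simulate_voxel_cohort(cfg$sim, n, sd),
    real_data = NULL)
  if (cfg$mode == "real_data") {
    full <- utils::read.csv(cfg$cohort_csv, stringsAsFactors = FALSE)
    need <- c("afp_high", "size_gt5", "multiple_tumors", "fd", "mvi",
              "rfs_months", "rfs_event", "os_months", "os_event")
    miss <- setdiff(need, names(full))
    if (length(miss) > 0L)
      stop("stage ingest: cohort CSV lacks column(s): ",
           paste(miss, collapse = ", "))
    if (nrow(full) < cfg$n_train + 10L)
      stop("stage ingest: cohort smaller than n_train + 10")
    train <- full[seq_len(cfg$n_train), ]
    test <- full[(cfg$n_train + 1L):nrow(full), ]
  } else {
    train <- get_cohort(cfg$n_train, seed_train)
    test <- get_cohort(cfg$n_test, seed_test)
  }
  log <- stage_log(log, "cohort", "train n=%d (MVI+ %d), test n=%d (MVI+ %d)",
                   nrow(train), sum(train$mvi), nrow(test), sum(test$mvi))

  candidates <- c("afp_high", "size_gt5", "multiple_tumors", "fd")
  uni <- lapply(candidates, function(v) fit_univariable(train, v))
  names(uni) <- candidates
  selected <- select_variables(uni, cfg$alpha)
  log <- stage_log(log, "screen", "univariable p<%g kept: %s", cfg$alpha,
                   paste(selected, collapse = ", "))

  clin_vars <- c("afp_high", "size_gt5", "multiple_tumors")
  models <- list(
    clinical = fit_multivariable(train, clin_vars),
    fd = fit_univariable(train, "fd"),
    combined = fit_multivariable(train, c(clin_vars, "fd")))
  vif <- compute_vif(train, c(clin_vars, "fd"))
  log <- stage_log(log, "models", "combined model VIF range %.3f-%.3f",
                   min(vif), max(vif))

  score <- function(fit, tab) predict_risk(fit, tab)$linear_predictor
  scores_train <- lapply(models, score, tab = train)
  scores_test <- lapply(models, score, tab = test)

  rocs <- lapply(scores_test, roc_auc_delong, labels = test$mvi)
  dl <- delong_paired_test(scores_test$combined, scores_test$clinical,
                           test$mvi)
  log <- stage_log(log, "roc",
                   "AUC fd=%.3f clinical=%.3f combined=%.3f (DeLong p=%.4g)",
                   rocs$fd$auc, rocs$clinical$auc, rocs$combined$auc, dl$p)

  hl <- hosmer_lemeshow(predict_risk(models$combined, test)$probability,
                        test$mvi, cfg$hl_groups)
  dca <- decision_curve(predict_risk(models$combined, test)$probability,
                        test$mvi)

  cut <- youden_cutoff(scores_train$combined, train$mvi)
  perf <- performance_at_cutoff(scores_test$combined, test$mvi,
                                cut$threshold)
  high <- scores_test$combined >= cut$threshold
  log <- stage_log(log, "stratify",
                   "Youden cut-off %.4f: %d high-risk / %d low-risk",
                   cut$threshold, sum(high), sum(!high))

  surv <- list()
  for (ep in c("rfs", "os")) {
    tcol <- paste0(ep, "_months"); ecol <- paste0(ep, "_event")
    lr <- logrank_test(test[[tcol]][high], test[[ecol]][high],
                       test[[tcol]][!high], test[[ecol]][!high])
    surv[[ep]] <- list(
      high = km_curve(test[[tcol]][high], test[[ecol]][high]),
      low = km_curve(test[[tcol]][!high], test[[ecol]][!high]),
      logrank = lr)
    log <- stage_log(log, "survival", "%s log-rank chi2=%.2f p=%.4g",
                     toupper(ep), lr$chi2, lr$p)
  }

  metrics <- list(
    seed = cfg$seed, config_hash = hash, mode = cfg$mode,
    n_train = nrow(train), n_test = nrow(test),
    mvi_prevalence_train = mean(train$mvi),
    mvi_prevalence_test = mean(test$mvi),
    fd_mean_mvi_pos = mean(train$fd[train$mvi == 1]),
    fd_mean_mvi_neg = mean(train$fd[train$mvi == 0]),
    selected_variables = selected,
    odds_ratios_combined = as.list(models$combined$or),
    vif = as.list(vif),
    auc = lapply(rocs, function(r) list(auc = r$auc, ci = r$ci)),
    delong_combined_vs_clinical = list(z = dl$z, p = dl$p),
    hosmer_lemeshow = list(chi2 = hl$chi2, df = hl$df, p = hl$p),
    youden = list(threshold = cut$threshold, j = cut$j,
                  sensitivity = unname(perf["sensitivity"]),
                  specificity = unname(perf["specificity"]),
                  accuracy = unname(perf["accuracy"])),
    survival = lapply(surv, function(s) list(
      logrank_chi2 = s$logrank$chi2, logrank_p = s$logrank$p,
      median_high = s$high$median, median_low = s$low$median)))

  report <- structure(list(metrics = metrics, models = models,
                           univariable = uni, rocs = rocs, delong = dl,
                           hosmer_lemeshow = hl, decision_curve = dca,
                           cutoff = cut, survival = surv,
                           train = train, test = test, log = log),
                      class = "study_report")

  if (!is.null(cfg$out_dir)) {
    od <- cfg$out_dir
    if (!dir.exists(od)) dir.create(od, recursive = TRUE)
    jsonlite::write_json(metrics, file.path(od, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    utils::write.csv(train, file.path(od, "cohort_train.csv"),
                     row.names = FALSE)
    utils::write.csv(test, file.path(od, "cohort_test.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(patient_id = test$patient_id,
                 score_clinical = scores_test$clinical,
                 score_fd = scores_test$fd,
                 score_combined = scores_test$combined,
                 high_risk = as.integer(high), mvi = test$mvi),
      file.path(od, "scores_test.csv"), row.names = FALSE)
    utils::write.csv(dca, file.path(od, "decision_curve.csv"),
                     row.names = FALSE)
    for (ep in c("rfs", "os")) {
      km <- rbind(
        data.frame(group = "high", time = surv[[ep]]$high$time,
                   n_risk = surv[[ep]]$high$n_risk,
                   surv = surv[[ep]]$high$surv),
        data.frame(group = "low", time = surv[[ep]]$low$time,
                   n_risk = surv[[ep]]$low$n_risk,
                   surv = surv[[ep]]$low$surv))
      utils::write.csv(km, file.path(od, paste0("km_", ep, ".csv")),
                       row.names = FALSE)
    }
    writeLines(c(sprintf("seed: %d", cfg$seed),
                 sprintf("config_hash: %s", hash),
                 sprintf("package: tumorfd %s",
                         as.character(utils::packageVersion("tumorfd"))),
                 log),
               file.path(od, "run_log.txt"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<study_report> %s, seed %d, hash %s\n", m$mode, m$seed,
              m$config_hash))
  cat(sprintf("  AUC: fd %.3f / clinical %.3f / combined %.3f\n",
              m$auc$fd$auc, m$auc$clinical$auc, m$auc$combined$auc))
  cat(sprintf("  DeLong combined vs clinical: p = %.4g\n",
              m$delong_combined_vs_clinical$p))
  cat(sprintf("  RFS log-rank p = %.4g, OS log-rank p = %.4g\n",
              m$survival$rfs$logrank_p, m$survival$os$logrank_p))
  invisible(x)
}
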