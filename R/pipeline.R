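# End-to-end pipeline driver and reporting.

pipeline_log <- function(lines, msg, ...) {
  line <- sprintf(msg, ...)
  message(line)
  c(lines, line)
}

#' Run the full severity analysis pipeline
#'
#' Simulates (or reads) a cohort, extracts the feature matrix, runs the
#' two-gate selection, classifies subscale associations, balances classes,
#' splits 70/30, fits the linear and random-forest models on the key
#' features, and writes all artefacts to `out_dir`:
#' `features.csv`, `registry.csv`, `selection.csv`, `subscales.json`,
#' `model_linear.json`, `model_random_forest.json`, `predictions.csv` and
#' `summary.log`. Deterministic given the config (reports contain no
#' timestamps). When no feature survives selection, model fitting is skipped
#' with an explanatory log line.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the cohort, feature matrix, selection
#'   result, subscale sets, model reports and the summary log lines.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "pipeline_config"))
    gw_validation_error("`config` must be a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)

  simulate <- is.null(config$waveforms_csv)
  cohort <- if (simulate) {
    log <- pipeline_log(log, "[simulate] seed %d: generating %s cohort",
                        config$cohort$seed,
                        paste(config$cohort$group_sizes, collapse = "/"))
    generate_cohort(config$cohort)
  } else {
    log <- pipeline_log(log, "[read] loading cohort from CSV")
    read_cohort(config$waveforms_csv, config$spatiotemporal_csv,
                config$womac_csv, toe_off_pct = config$toe_off_pct)
  }
  n <- cohort_size(cohort)
  log <- pipeline_log(log, "[cohort] %d subjects", n)

  registry <- build_feature_registry(config$registry)
  fm <- extract_features(cohort, registry,
                         obw_fraction = config$obw_fraction,
                         dtw_cost = config$dtw_cost)
  log <- pipeline_log(log, "[extract] %d features x %d subjects (%s registry)",
                      ncol(fm$values), n, config$registry)
  write_feature_csv(fm, file.path(out_dir, "features.csv"),
                    file.path(out_dir, "registry.csv"))

  totals <- cohort_womac_totals(cohort)
  classes <- classify_scale_scores(totals, "total")
  log <- pipeline_log(log, "[classes] mild/moderate/severe = %s",
                      paste(table(classes), collapse = "/"))

  fm_clean <- drop_masked_features(fm)
  if (ncol(fm_clean$values) < ncol(fm$values))
    log <- pipeline_log(log, "[extract] %d feature(s) dropped for undefined values",
                        ncol(fm$values) - ncol(fm_clean$values))
  sel <- select_features(fm_clean, classes,
                         alpha_anova = config$alpha_anova,
                         alpha_pairwise = config$alpha_pairwise)
  keys <- select_key_features(sel)
  log <- pipeline_log(log, "[select] %d passed ANOVA (alpha %g), %d key features (alpha %g)",
                      sum(sel$table$passed), config$alpha_anova,
                      length(keys), config$alpha_pairwise)
  data.table::fwrite(sel$table, file.path(out_dir, "selection.csv"))

  result <- list(cohort = cohort, features = fm, selection = sel,
                 key_features = keys, subscales = NULL,
                 linear = NULL, random_forest = NULL)

  if (!length(keys)) {
    log <- pipeline_log(log,
      "[models] no key features selected; model fitting skipped")
    writeLines(log, file.path(out_dir, "summary.log"))
    result$log <- log
    return(invisible(result))
  }

  subs <- subscale_association(fm_clean, cohort$womac, keys,
                               alpha_anova = config$alpha_anova,
                               alpha_pairwise = config$alpha_pairwise)
  log <- pipeline_log(log, "[subscales] significant features: pain %s, stiffness %s, physical function %s",
                      fmt_count(subs$pain), fmt_count(subs$stiffness),
                      fmt_count(subs$physical_function))
  jsonlite::write_json(lapply(subs, function(x) if (is.null(x)) NA else x),
                       file.path(out_dir, "subscales.json"), auto_unbox = FALSE,
                       pretty = TRUE)
  result$subscales <- subs

  keep <- balance_downsample(cohort$subject_ids, classes,
                             target_total = config$balance_target,
                             seed = config$seed_balance)
  cls_keep <- classes[match(keep, cohort$subject_ids)]
  log <- pipeline_log(log, "[balance] down-sampled %d -> %d (%s)",
                      n, length(keep), paste(table(cls_keep), collapse = "/"))
  split <- holdout_split(keep, cls_keep, train_fraction = config$train_fraction,
                         seed = config$seed_split)
  log <- pipeline_log(log, "[split] train %d / test %d",
                      length(split$train), length(split$test))

  model_feats <- head(keys, config$max_model_features)
  if (length(model_feats) < length(keys))
    log <- pipeline_log(log, "[models] using top %d of %d key features (by ANOVA p)",
                        length(model_feats), length(keys))

  lin <- fit_linear(fm_clean, unname(totals), model_feats,
                    split$train, split$test, allow_rank_deficient = TRUE)
  log <- pipeline_log(log, "[linear] hold-out RMSE %.2f, r %.3f (in-sample RMSE %.2f, r %.3f)",
                      lin$rmse, lin$pearson_r, lin$rmse_train, lin$pearson_r_train)
  rf <- fit_random_forest(fm_clean, unname(totals), model_feats,
                          split$train, split$test, seed = config$seed_forest)
  log <- pipeline_log(log, "[random_forest] hold-out RMSE %.2f, r %.3f",
                      rf$rmse, rf$pearson_r)

  for (m in list(lin, rf)) {
    jsonlite::write_json(
      list(model_kind = m$model_kind, n_train = m$n_train, n_test = m$n_test,
           rmse = m$rmse, pearson_r = m$pearson_r,
           rmse_train = m$rmse_train, pearson_r_train = m$pearson_r_train,
           seed = m$seed, hyperparameters = m$hyperparameters,
           features = m$feature_ids,
           coefficients = m$coefficients),
      file.path(out_dir, sprintf("model_%s.json", m$model_kind)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  preds <- rbind(cbind(model = "linear", lin$predictions),
                 cbind(model = "random_forest", rf$predictions))
  data.table::fwrite(preds, file.path(out_dir, "predictions.csv"))
  writeLines(log, file.path(out_dir, "summary.log"))
  result$linear <- lin; result$random_forest <- rf; result$log <- log
  invisible(result)
}

fmt_count <- function(x) if (is.null(x)) "unevaluable" else as.character(length(x))

#' Plot group-mean waveforms of one gait parameter
#'
#' Mean curve per severity class with a +/- 1 SD band, on the normalized
#' cycle axis.
#'
#' @param cohort A `gait_cohort`.
#' @param parameter Gait parameter name.
#' @param classes Optional severity factor (defaults to classes derived from
#'   the cohort's WOMAC totals).
#' @param file Optional PNG path; when given the plot is written there.
#' @return Invisibly, the matrix of group means (101 x 3).
#' @export
plot_group_means <- function(cohort, parameter, classes = NULL, file = NULL) {
  if (!parameter %in% names(cohort$waveforms))
    gw_validation_error(sprintf("unknown gait parameter '%s'", parameter))
  if (is.null(classes))
    classes <- classify_scale_scores(cohort_womac_totals(cohort), "total")
  M <- cohort$waveforms[[parameter]]
  lev <- severity_levels()
  cols <- c(mild = "#1b9e77", moderate = "#d95f02", severe = "#7570b3")
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off())
  }
  means <- sapply(lev, function(g) rowMeans(M[, classes == g, drop = FALSE]))
  sds <- sapply(lev, function(g) apply(M[, classes == g, drop = FALSE], 1, sd))
  graphics::matplot(GW_CYCLE_AXIS, means, type = "l", lty = 1, lwd = 2,
                    col = cols[lev], xlab = "gait cycle (%)",
                    ylab = parameter, main = parameter)
  for (g in lev)
    graphics::polygon(c(GW_CYCLE_AXIS, rev(GW_CYCLE_AXIS)),
                      c(means[, g] + sds[, g], rev(means[, g] - sds[, g])),
                      col = grDevices::adjustcolor(cols[g], alpha.f = 0.15),
                      border = NA)
  graphics::legend("topright", legend = lev, col = cols[lev], lwd = 2, bty = "n")
  invisible(means)
}
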