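# CSV and configuration I/O.
#
# Interchange formats (all plain text):
#   waveforms CSV (long): subject_id, parameter, cycle_pct, value
#   spatiotemporal CSV (long): subject_id, name, value
#   WOMAC CSV (wide): subject_id, item_01..item_24
#   phase CSV (optional): subject_id, toe_off_pct
#   config: flat "key = value" lines

#' Write a cohort to CSV files
#'
#' @param cohort A `gait_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of file paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(waveforms = file.path(dir, "waveforms.csv"),
                spatiotemporal = file.path(dir, "spatiotemporal.csv"),
                womac = file.path(dir, "womac.csv"))
  n <- cohort_size(cohort)
  wf <- data.table::rbindlist(lapply(names(cohort$waveforms), function(p)
    data.table::data.table(
      subject_id = rep(cohort$subject_ids, each = 101L),
      parameter = p,
      cycle_pct = rep(GW_CYCLE_AXIS, times = n),
      value = as.vector(cohort$waveforms[[p]]))))
  data.table::fwrite(wf, paths$waveforms)
  sp <- data.table::data.table(
    subject_id = rep(cohort$subject_ids, times = ncol(cohort$spatiotemporal)),
    name = rep(names(cohort$spatiotemporal), each = n),
    value = unlist(cohort$spatiotemporal, use.names = FALSE))
  data.table::fwrite(sp, paths$spatiotemporal)
  data.table::fwrite(cohort$womac, paths$womac)
  invisible(paths)
}

#' Read a cohort from CSV files
#'
#' Subjects are joined on `subject_id` across the three tables; subjects
#' missing from any table are dropped with a message stating the count
#' (mirroring the exclusion of subjects with incomplete records). Malformed
#' rows raise validation errors naming the file and problem.
#'
#' @param waveforms,spatiotemporal,womac File paths of the three CSVs.
#' @param toe_off_pct Stance/swing boundary for the phase map (default 60).
#' @return A `gait_cohort`.
#' @export
read_cohort <- function(waveforms, spatiotemporal, womac, toe_off_pct = 60) {
  wf <- data.table::fread(waveforms)
  sp <- data.table::fread(spatiotemporal)
  wo <- data.table::fread(womac)
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      gw_validation_error(sprintf("%s: missing column(s) %s", file,
                                  paste(miss, collapse = ", ")))
  }
  need(wf, c("subject_id", "parameter", "cycle_pct", "value"), waveforms)
  need(sp, c("subject_id", "name", "value"), spatiotemporal)
  item_cols <- sprintf("item_%02d", 1:24)
  need(wo, c("subject_id", item_cols), womac)
  if (anyDuplicated(wo$subject_id))
    gw_validation_error(sprintf("%s: duplicated subject_id", womac))
  for (ic in item_cols) {
    v <- wo[[ic]]
    bad <- which(is.na(v) | v < 0 | v > 4 | v != round(v))
    if (length(bad))
      gw_validation_error(sprintf("%s: invalid value in %s (row %d)",
                                  womac, ic, bad[1]))
  }
  ids <- Reduce(intersect, list(unique(wf$subject_id), unique(sp$subject_id),
                                wo$subject_id))
  dropped <- length(unique(c(wf$subject_id, sp$subject_id, wo$subject_id))) -
    length(ids)
  if (dropped > 0)
    message(sprintf("dropping %d subject(s) missing from some input table", dropped))
  if (!length(ids))
    gw_validation_error("no subjects present in all three input tables")
  ids <- sort(ids)
  n <- length(ids)

  params <- unique(wf$parameter)
  cycle_pct <- value <- subject_id <- parameter <- NULL  # NSE notes
  wfs <- lapply(params, function(p) {
    sub <- wf[parameter == p & subject_id %in% ids]
    if (nrow(sub) != 101L * n || anyDuplicated(sub[, list(subject_id, cycle_pct)])) {
      counts <- table(sub$subject_id)
      off <- names(counts)[counts != 101L][1]
      have <- sub$cycle_pct[sub$subject_id == off]
      gw_validation_error(sprintf(
        "%s: parameter '%s', subject '%s' has %d of 101 cycle positions (missing: %s)",
        waveforms, p, off, length(have),
        paste(head(setdiff(GW_CYCLE_AXIS, have), 10), collapse = ", ")))
    }
    data.table::setorder(sub, subject_id, cycle_pct)
    matrix(sub$value, nrow = 101L, ncol = n,
           dimnames = list(NULL, sort(unique(sub$subject_id))))[, ids, drop = FALSE]
  })
  names(wfs) <- params

  spw <- data.table::dcast(sp[subject_id %in% ids], subject_id ~ name,
                           value.var = "value")
  data.table::setorder(spw, subject_id)
  spdf <- as.data.frame(spw[, -1])
  wo <- as.data.frame(wo)[match(ids, wo$subject_id), , drop = FALSE]
  rownames(wo) <- NULL
  gait_cohort(ids, wfs, spdf, wo,
              phase_map = default_phase_map(toe_off_pct))
}

#' Write a feature matrix and its registry to CSV
#' @param fm A `feature_matrix`.
#' @param features_path,registry_path Output file paths.
#' @return Invisibly, the feature file path.
#' @export
write_feature_csv <- function(fm, features_path, registry_path = NULL) {
  df <- data.table::data.table(subject_id = fm$subject_ids, fm$values)
  data.table::fwrite(df, features_path)
  if (!is.null(registry_path))
    data.table::fwrite(fm$registry, registry_path)
  invisible(features_path)
}

# Pipeline configuration ------------------------------------------------------

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. All stochastic stages have
#' explicit seeds. `cohort` holds a [cohort_config()] for simulated input;
#' alternatively `waveforms_csv`/`spatiotemporal_csv`/`womac_csv` point at
#' files on disk.
#'
#' @param registry `"full"` or `"table2"`.
#' @param alpha_anova,alpha_pairwise Selection gate levels.
#' @param balance_target Class-balanced total (default 231).
#' @param train_fraction Hold-out training fraction (default 0.70).
#' @param max_model_features Cap on the number of key features entering the
#'   regression models (top by ANOVA p); keeps the linear design full rank.
#' @param seed_balance,seed_split,seed_forest Stage seeds.
#' @param toe_off_pct Stance/swing boundary.
#' @param obw_fraction Occupied-bandwidth power fraction.
#' @param dtw_cost DTW local cost (`"absolute"` or `"squared"`).
#' @param cohort A [cohort_config()] (used when no CSV paths are given).
#' @param waveforms_csv,spatiotemporal_csv,womac_csv Optional input paths.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(registry = "full",
                            alpha_anova = GW_ALPHA_ANOVA,
                            alpha_pairwise = GW_ALPHA_PAIRWISE,
                            balance_target = 231L,
                            train_fraction = 0.70,
                            max_model_features = 50L,
                            seed_balance = 21L,
                            seed_split = 22L,
                            seed_forest = 23L,
                            toe_off_pct = 60,
                            obw_fraction = 0.99,
                            dtw_cost = "absolute",
                            cohort = cohort_config(),
                            waveforms_csv = NULL,
                            spatiotemporal_csv = NULL,
                            womac_csv = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write a pipeline configuration as flat key = value text
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- config
  cc <- flat$cohort
  flat$cohort <- NULL
  lines <- character(0)
  emit <- function(prefix, x) {
    for (nm in names(x)) {
      v <- x[[nm]]
      # only flat scalar/vector fields serialise; template objects keep their
      # in-code defaults
      if (is.null(v) || !is.atomic(v)) next
      lines <<- c(lines, sprintf("%s%s = %s", prefix, nm,
                                 paste(format(v, digits = 17), collapse = ",")))
    }
  }
  emit("", flat[!vapply(flat, is.null, logical(1))])
  if (!is.null(cc)) emit("cohort.", unclass(cc))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline configuration from flat key = value text
#' @param path Input path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- lapply(strsplit(lines, "=", fixed = TRUE), function(x)
    c(trimws(x[1]), trimws(paste(x[-1], collapse = "="))))
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  parse_val <- function(v, template) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    if (is.numeric(template)) as.numeric(parts)
    else if (is.integer(template)) as.integer(parts)
    else parts
  }
  cfg <- pipeline_config()
  cc <- cfg$cohort
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (startsWith(k, "cohort.")) {
      f <- sub("^cohort\\.", "", k)
      if (f %in% names(cc)) cc[[f]] <- parse_val(vals[i], cc[[f]])
    } else if (k %in% names(cfg)) {
      cfg[[k]] <- parse_val(vals[i], cfg[[k]])
    }
  }
  # integer-typed fields
  for (f in c("balance_target", "max_model_features", "seed_balance",
              "seed_split", "seed_forest"))
    cfg[[f]] <- as.integer(cfg[[f]])
  cc$group_sizes <- as.integer(cc$group_sizes)
  cc$seed <- as.integer(cc$seed)
  cfg$cohort <- structure(cc, class = "cohort_config")
  structure(cfg, class = "pipeline_config")
}
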