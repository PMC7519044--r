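# Cohort container and feature-matrix extraction.
#
# A `gait_cohort` stores the right-leg waveforms of all subjects as
# per-parameter 101 x n matrices (one column per subject), the spatiotemporal
# scalars as an n-row data frame, and the WOMAC item table. Extraction is
# vectorised across subjects per (parameter, window, operator) group, so a
# full-grid matrix for hundreds of subjects takes well under a second.

#' Assemble a gait cohort container
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param waveforms Named list, one entry per gait parameter, each a numeric
#'   matrix with 101 rows (cycle positions 0..100) and one column per subject.
#' @param spatiotemporal data.frame of scalar gait characteristics, one row
#'   per subject (columns named as in [spatiotemporal_parameters()]).
#' @param womac data.frame with `subject_id` and `item_01`..`item_24`.
#' @param phase_map A `phase_map` (default toe-off 60%).
#' @param meta Optional per-subject metadata data.frame (e.g. generating group
#'   and latent severity for synthetic cohorts).
#' @return A `gait_cohort`.
#' @export
gait_cohort <- function(subject_ids, waveforms, spatiotemporal, womac,
                        phase_map = default_phase_map(), meta = NULL) {
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids))
    gw_validation_error("duplicated subject_id in cohort")
  for (p in names(waveforms)) {
    w <- waveforms[[p]]
    if (!is.matrix(w) || nrow(w) != 101L || ncol(w) != n)
      gw_validation_error(sprintf(
        "waveform matrix for '%s' must be 101 x %d", p, n))
    if (!all(is.finite(w)))
      gw_validation_error(sprintf("non-finite waveform values for '%s'", p))
  }
  if (nrow(spatiotemporal) != n)
    gw_validation_error("spatiotemporal table must have one row per subject")
  if (nrow(womac) != n)
    gw_validation_error("WOMAC table must have one row per subject")
  structure(list(subject_ids = as.character(subject_ids),
                 waveforms = waveforms,
                 spatiotemporal = spatiotemporal,
                 womac = womac,
                 phase_map = phase_map,
                 meta = meta),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("Gait cohort: %d subjects, %d waveform parameters, %d spatiotemporal scalars\n",
              length(x$subject_ids), length(x$waveforms), ncol(x$spatiotemporal)))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `gait_cohort`.
#' @return Integer subject count.
#' @export
cohort_size <- function(cohort) length(cohort$subject_ids)

#' WOMAC total scores of a cohort
#' @param cohort A `gait_cohort`.
#' @return Named integer vector of totals (names are subject ids).
#' @export
cohort_womac_totals <- function(cohort) {
  item_cols <- sprintf("item_%02d", 1:24)
  tot <- as.integer(rowSums(cohort$womac[, item_cols]))
  setNames(tot, cohort$subject_ids)
}

#' Extract one subject's trial from a cohort
#'
#' @param cohort A `gait_cohort`.
#' @param i Subject index or id.
#' @return A `gait_trial`: list with `subject_id`, `side` (always "right"),
#'   `waveforms` (named list of `gait_waveform`), `spatiotemporal` (named
#'   numeric) and `phase_map`.
#' @export
get_trial <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$subject_ids)
  if (is.na(i) || i < 1 || i > cohort_size(cohort))
    gw_validation_error("subject not found in cohort")
  units <- setNames(gait_parameters()$units, gait_parameters()$parameter)
  wf <- lapply(names(cohort$waveforms), function(p)
    gait_waveform(cohort$waveforms[[p]][, i], p, unname(units[p])))
  names(wf) <- names(cohort$waveforms)
  structure(list(subject_id = cohort$subject_ids[i],
                 side = "right",
                 waveforms = wf,
                 spatiotemporal = unlist(cohort$spatiotemporal[i, , drop = TRUE]),
                 phase_map = cohort$phase_map),
            class = "gait_trial")
}

# column-wise summary statistics of a slice matrix (m samples x n subjects);
# undefined statistics become NA (recorded in the mask by the caller)
matrix_summary_stats <- function(S) {
  m <- nrow(S); n <- ncol(S)
  cm <- colMeans(S)
  Sc <- S - rep(cm, each = m)
  m2 <- colMeans(Sc^2)
  v <- m2 * m / (m - 1)
  msq <- colMeans(S^2)
  rms <- sqrt(msq)
  Sa <- abs(S)
  ca <- colMeans(Sa)
  va <- (colMeans(Sa^2) - ca^2) * m / (m - 1)
  va[va < 0] <- 0
  mx <- apply(S, 2, max)
  mn <- apply(S, 2, min)
  peak <- pmax(abs(mx), abs(mn))
  kurt <- ifelse(m2 > 0 & m >= 4, colMeans(Sc^4) / m2^2, NA_real_)
  list(mean = cm,
       mean_abs = ca,
       sd = sqrt(v),
       sd_abs = sqrt(va),
       variance = v,
       rms = rms,
       peak2rms = ifelse(rms > 0, peak / rms, NA_real_),
       kurtosis = kurt,
       max = mx,
       min = mn,
       max_minus_min = mx - mn)
}

matrix_psd_features <- function(M, fraction = 0.99) {
  m <- nrow(M); n <- ncol(M)
  Mc <- M - rep(colMeans(M), each = m)
  X <- mvfft(Mc)
  dens2 <- Mod(X)^2 / m
  psd_auc <- colSums(dens2) / m   # exact trapezoid over the periodic grid
  kmax <- m %/% 2
  df <- 1 / m
  out_l <- out_u <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    if (psd_auc[j] <= 0) next
    p <- dens2[seq_len(kmax + 1), j] * df
    sc <- 2:(kmax + 1)
    if (m %% 2 == 0) sc <- sc[-length(sc)]
    p[sc] <- 2 * p[sc]
    cum <- cumsum(p)
    tot <- cum[length(cum)]
    tail_frac <- (1 - fraction) / 2
    edge <- function(target) {
      k <- which(cum >= target)[1]
      prev <- if (k > 1) cum[k - 1] else 0
      max(0, (k - 1) * df - df / 2 + df * (target - prev) / p[k])
    }
    out_l[j] <- edge(tail_frac * tot)
    out_u[j] <- edge((1 - tail_frac) * tot)
  }
  list(psd_auc = ifelse(psd_auc > 0, psd_auc, NA_real_),
       occupied_bandwidth = out_u - out_l,
       bandwidth_lower_bound = out_l,
       bandwidth_upper_bound = out_u)
}

matrix_acf_lower_bound <- function(M) {
  m <- nrow(M); n <- ncol(M)
  Mc <- M - rep(colMeans(M), each = m)
  denom <- colSums(Mc^2)
  nfft <- 2^ceiling(log2(2 * m))
  A <- mvfft(rbind(Mc, matrix(0, nfft - m, n)))
  ac <- Re(mvfft(A * Conj(A), inverse = TRUE)) / nfft
  r <- ac[2:m, , drop = FALSE] / rep(denom, each = m - 1)
  out <- apply(r, 2, min)
  out[denom == 0] <- NA_real_
  out
}

#' Extract the subjects x features matrix of a cohort
#'
#' Computes every feature of the registry for every subject, vectorised
#' across subjects. Undefined statistics (zero variance, zero RMS) are
#' recorded as `NA` in the values with the corresponding entry of the missing
#' mask set.
#'
#' @param cohort A `gait_cohort`.
#' @param registry Feature registry from [build_feature_registry()].
#' @param obw_fraction Occupied-bandwidth power fraction (default 0.99).
#' @param dtw_cost Local DTW cost, `"absolute"` or `"squared"`.
#' @return A `feature_matrix`: list with `subject_ids`, `registry`, `values`
#'   (n x p numeric matrix, feature ids as column names) and `mask` (logical,
#'   `TRUE` where undefined).
#' @export
extract_features <- function(cohort, registry = build_feature_registry("full"),
                             obw_fraction = 0.99,
                             dtw_cost = "absolute") {
  if (!inherits(cohort, "gait_cohort"))
    gw_validation_error("`cohort` must be a gait_cohort")
  n <- cohort_size(cohort)
  p <- nrow(registry)
  vals <- matrix(NA_real_, n, p,
                 dimnames = list(cohort$subject_ids, registry$feature_id))
  pm <- cohort$phase_map
  for (param in unique(registry$parameter)) {
    rows <- which(registry$parameter == param)
    ops <- registry$operator[rows]
    wins <- registry$window[rows]
    if (all(ops == "value")) {
      if (!param %in% names(cohort$spatiotemporal))
        gw_validation_error(sprintf("unknown spatiotemporal parameter '%s'", param))
      vals[, rows] <- as.numeric(cohort$spatiotemporal[[param]])
      next
    }
    if (!param %in% names(cohort$waveforms))
      gw_validation_error(sprintf("unknown gait parameter '%s'", param))
    M <- cohort$waveforms[[param]]
    # windowed statistics and extrema/areas
    for (w in unique(wins[ops %in% c(GW_SUMMARY_STATS, "auc")])) {
      idx <- phase_window_idx(pm, w)
      S <- M[idx, , drop = FALSE]
      here <- rows[wins == w & ops %in% c(GW_SUMMARY_STATS, "auc")]
      need <- registry$operator[here]
      if (any(need %in% GW_SUMMARY_STATS)) {
        st <- matrix_summary_stats(S)
        for (k in which(need %in% GW_SUMMARY_STATS))
          vals[, here[k]] <- st[[need[k]]]
      }
      if ("auc" %in% need) {
        tw <- trapz_weights(GW_CYCLE_AXIS[idx])
        vals[, here[need == "auc"]] <- colSums(S * tw)
      }
    }
    # whole-signal spectral / autocorrelation / level / DTW features
    spec_ops <- c("psd_auc", "occupied_bandwidth", "bandwidth_lower_bound",
                  "bandwidth_upper_bound")
    if (any(ops %in% spec_ops)) {
      ps <- matrix_psd_features(M, fraction = obw_fraction)
      for (k in which(ops %in% spec_ops))
        vals[, rows[k]] <- ps[[ops[k]]]
    }
    if ("autocorr_lower_bound" %in% ops)
      vals[, rows[ops == "autocorr_lower_bound"]] <- matrix_acf_lower_bound(M)
    if ("mid_reference_level" %in% ops)
      vals[, rows[ops == "mid_reference_level"]] <-
        apply(M, 2, mid_reference_level)
    if ("dtw_stance_swing" %in% ops) {
      ia <- phase_window_idx(pm, "stance"); ib <- phase_window_idx(pm, "swing")
      sq <- identical(dtw_cost, "squared")
      d <- vapply(seq_len(n), function(j)
        .dtw_cost_cpp(M[ia, j], M[ib, j], sq), numeric(1))
      vals[, rows[ops == "dtw_stance_swing"]] <- d
    }
    unknown <- setdiff(ops, c(GW_SUMMARY_STATS, "auc", spec_ops, "value",
                              "autocorr_lower_bound", "mid_reference_level",
                              "dtw_stance_swing", "min", "max"))
    if (length(unknown))
      gw_validation_error(sprintf("unknown operator(s): %s",
                                  paste(unique(unknown), collapse = ", ")))
  }
  structure(list(subject_ids = cohort$subject_ids,
                 registry = registry,
                 values = vals,
                 mask = is.na(vals)),
            class = "feature_matrix")
}

#' Extract one feature row for a single trial
#'
#' @param trial A `gait_trial` (see [get_trial()]).
#' @param registry Feature registry.
#' @param ... Passed to [extract_features()].
#' @return Named numeric vector, one value per registry row (NA where
#'   undefined), with the missing mask as attribute `"mask"`.
#' @export
extract_all <- function(trial, registry = build_feature_registry("full"), ...) {
  if (!inherits(trial, "gait_trial"))
    gw_validation_error("`trial` must be a gait_trial")
  if (nrow(registry) == 0L)
    return(structure(numeric(0), mask = logical(0)))
  wf <- lapply(trial$waveforms, function(w) matrix(w$values, ncol = 1))
  sp <- as.data.frame(as.list(trial$spatiotemporal))
  womac <- as.data.frame(setNames(as.list(rep(0L, 25)),
                                  c("subject_id", sprintf("item_%02d", 1:24))))
  womac$subject_id <- trial$subject_id
  mini <- gait_cohort(trial$subject_id, wf, sp, womac, trial$phase_map)
  fm <- extract_features(mini, registry, ...)
  structure(setNames(fm$values[1, ], registry$feature_id),
            mask = fm$mask[1, ])
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d subjects x %d features (%d masked values)\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' Drop features with any masked (undefined) value
#'
#' Features whose value is undefined for at least one subject are removed
#' before statistical selection, with a message stating the count.
#'
#' @param fm A `feature_matrix`.
#' @return A `feature_matrix` restricted to fully observed features.
#' @export
drop_masked_features <- function(fm) {
  bad <- colSums(fm$mask) > 0
  if (any(bad))
    message(sprintf("dropping %d feature(s) with undefined values before selection",
                    sum(bad)))
  structure(list(subject_ids = fm$subject_ids,
                 registry = fm$registry[!bad, , drop = FALSE],
                 values = fm$values[, !bad, drop = FALSE],
                 mask = fm$mask[, !bad, drop = FALSE]),
            class = "feature_matrix")
}
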