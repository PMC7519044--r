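# Parameter and feature registries.
#
# Feature ids are canonical strings "parameter.operator.window" (window
# omitted for whole-signal and scalar features). The default "full" registry
# is the operator-family x applicable-window x parameter grid (1060 features);
# the "table2" registry pins the 42 named key features reported for the
# severity analysis as a documented sub-registry.

#' Registered gait waveform parameters
#'
#' The twelve right-leg kinematic/kinetic gait-cycle parameters analysed by
#' the pipeline, with units.
#'
#' @return data.frame with columns `parameter` and `units`.
#' @export
gait_parameters <- function() {
  data.frame(
    parameter = c("hip_rotation_moment", "hip_flexion_angle",
                  "hip_adduction_angle", "hip_power",
                  "pelvic_obliquity_angle",
                  "knee_extension_moment", "knee_flexion_angle", "knee_power",
                  "knee_varus_angle",
                  "ankle_plantarflexion_moment", "ankle_power",
                  "foot_progression_angle"),
    units = c("N*m/kg", "deg", "deg", "W/kg", "deg",
              "N*m/kg", "deg", "W/kg", "deg",
              "N*m/kg", "W/kg", "deg"),
    stringsAsFactors = FALSE)
}

#' Registered spatiotemporal gait characteristics
#'
#' Sixteen scalar gait characteristics carried as identity features
#' alongside the waveform-derived features.
#'
#' @return data.frame with columns `parameter` and `units`.
#' @export
spatiotemporal_parameters <- function() {
  data.frame(
    parameter = c("total_speed", "cadence", "stride_length", "step_length",
                  "step_width", "stride_time", "step_time",
                  "stance_phase_pct", "swing_phase_pct",
                  "single_limb_support", "initial_double_limb_support",
                  "terminal_double_limb_support", "weight_acceptance",
                  "push_off_timing", "gait_cycle_duration",
                  "opposite_foot_contact"),
    units = c("cm/s", "steps/min", "cm", "cm", "cm", "s", "s",
              "%cycle", "%cycle", "%cycle", "%cycle", "%cycle", "%cycle",
              "%cycle", "s", "%cycle"),
    stringsAsFactors = FALSE)
}

gw_feature_id <- function(parameter, operator, window) {
  n <- max(length(parameter), length(operator), length(window))
  parameter <- rep_len(parameter, n)
  operator <- rep_len(operator, n)
  window <- rep_len(window, n)
  ifelse(window == "full" | window == "" | is.na(window),
         paste(parameter, operator, sep = "."),
         paste(parameter, operator, window, sep = "."))
}

new_registry_rows <- function(parameter, operator, window, units) {
  data.frame(feature_id = gw_feature_id(parameter, operator, window),
             parameter = parameter, operator = operator, window = window,
             units = units, stringsAsFactors = FALSE)
}

#' Build a feature registry
#'
#' `kind = "full"` enumerates the default operator grid over all registered
#' waveform parameters (eleven summary statistics on full/stance/swing;
#' mean, SD and range on each of the seven sub-phases; extrema on the seven
#' sub-phases and the compound terminal-stance-to-pre-swing window; areas
#' under the curve on full/stance/swing and each sub-phase; four
#' spectral features; autocorrelation lower bound; mid-reference level; DTW
#' stance-vs-swing) plus the sixteen spatiotemporal identity features --
#' 1060 features in total. `kind = "table2"` returns the 42 named key
#' features of the severity analysis.
#'
#' @param kind `"full"` or `"table2"`.
#' @return data.frame registry: `feature_id`, `parameter`, `operator`,
#'   `window`, `units`; attribute `"registry_kind"` records the kind.
#' @export
#' @examples
#' nrow(build_feature_registry("full"))
build_feature_registry <- function(kind = c("full", "table2")) {
  kind <- match.arg(kind)
  reg <- if (kind == "full") registry_full_grid() else registry_table2()
  if (anyDuplicated(reg$feature_id))
    gw_error("duplicated feature ids in registry", "gw_internal_error")
  attr(reg, "registry_kind") <- kind
  reg
}

registry_full_grid <- function() {
  gp <- gait_parameters()
  out <- vector("list", nrow(gp) + 1L)
  for (i in seq_len(nrow(gp))) {
    p <- gp$parameter[i]; u <- gp$units[i]
    rows <- rbind(
      new_registry_rows(p, rep(GW_SUMMARY_STATS, times = 3),
                        rep(c("full", "stance", "swing"), each = length(GW_SUMMARY_STATS)), u),
      new_registry_rows(p, rep(c("mean", "sd", "max_minus_min"), each = 7),
                        rep(GW_SUBPHASES, times = 3), u),
      new_registry_rows(p, rep(c("min", "max"), each = 8),
                        rep(c(GW_SUBPHASES, "terminal_stance_pre_swing"), times = 2), u),
      new_registry_rows(p, "auc", c("full", "stance", "swing", GW_SUBPHASES),
                        paste0(u, "*%")),
      new_registry_rows(p, c("psd_auc", "occupied_bandwidth",
                             "bandwidth_lower_bound", "bandwidth_upper_bound"),
                        "full", c(paste0("(", u, ")^2"), rep("cycles/%", 3))),
      new_registry_rows(p, c("autocorr_lower_bound", "mid_reference_level",
                             "dtw_stance_swing"),
                        "full", c("1", u, u)))
    out[[i]] <- rows
  }
  sp <- spatiotemporal_parameters()
  out[[nrow(gp) + 1L]] <- new_registry_rows(sp$parameter, "value", "full", sp$units)
  do.call(rbind, out)
}

registry_table2 <- function() {
  spec <- list(
    c("hip_rotation_moment", "sd", "full"),
    c("hip_flexion_angle", "autocorr_lower_bound", "full"),
    c("hip_flexion_angle", "bandwidth_lower_bound", "full"),
    c("hip_adduction_angle", "auc", "stance"),
    c("hip_adduction_angle", "sd_abs", "full"),
    c("hip_power", "min", "mid_stance"),
    c("hip_power", "max", "terminal_stance"),
    c("hip_power", "auc", "full"),
    c("hip_power", "max_minus_min", "full"),
    c("hip_power", "dtw_stance_swing", "full"),
    c("hip_power", "max", "mid_swing"),
    c("hip_power", "min", "terminal_swing"),
    c("pelvic_obliquity_angle", "min", "terminal_stance_pre_swing"),
    c("knee_extension_moment", "kurtosis", "full"),
    c("knee_extension_moment", "peak2rms", "full"),
    c("knee_flexion_angle", "variance", "full"),
    c("knee_flexion_angle", "sd", "full"),
    c("knee_flexion_angle", "max_minus_min", "full"),
    c("knee_flexion_angle", "psd_auc", "full"),
    c("knee_power", "max", "terminal_swing"),
    c("knee_varus_angle", "max", "mid_stance"),
    c("knee_varus_angle", "max", "terminal_stance"),
    c("knee_varus_angle", "auc", "stance"),
    c("knee_varus_angle", "auc", "full"),
    c("knee_varus_angle", "rms", "full"),
    c("knee_varus_angle", "peak2rms", "full"),
    c("knee_varus_angle", "mid_reference_level", "full"),
    c("knee_varus_angle", "psd_auc", "full"),
    c("knee_varus_angle", "max", "terminal_swing"),
    c("knee_varus_angle", "min", "loading_response"),
    c("ankle_plantarflexion_moment", "min", "loading_response"),
    c("ankle_plantarflexion_moment", "max", "initial_swing"),
    c("ankle_plantarflexion_moment", "max_minus_min", "full"),
    c("ankle_power", "kurtosis", "full"),
    c("ankle_power", "peak2rms", "full"),
    c("ankle_power", "max_minus_min", "full"),
    c("ankle_power", "autocorr_lower_bound", "full"),
    c("ankle_power", "occupied_bandwidth", "full"),
    c("foot_progression_angle", "mean_abs", "full"),
    c("total_speed", "value", "full"),
    c("single_limb_support", "value", "full"),
    c("initial_double_limb_support", "value", "full"))
  units <- setNames(c(gait_parameters()$units, spatiotemporal_parameters()$units),
                    c(gait_parameters()$parameter, spatiotemporal_parameters()$parameter))
  m <- do.call(rbind, spec)
  new_registry_rows(m[, 1], m[, 2], m[, 3], unname(units[m[, 1]]))
}
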