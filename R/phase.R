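# Gait-cycle axis, normalisation, and stance/swing sub-phase segmentation.
#
# Waveforms live on a fixed 101-point cycle axis (0..100% inclusive, one
# sample per percent), the dominant gait-lab reporting convention. The cycle
# is split at toe-off (default 60%) into stance and swing; stance carries the
# loading response / mid-stance / terminal stance / pre-swing sub-phases in
# 1:2:2:1 proportions (the standard percentages 0/10/30/50/60 at toe-off 60),
# and swing is split into initial/mid/terminal thirds.

GW_CYCLE_AXIS <- 0:100

GW_SUBPHASES <- c("loading_response", "mid_stance", "terminal_stance",
                  "pre_swing", "initial_swing", "mid_swing", "terminal_swing")

#' Normalise raw stride samples onto the 101-point gait-cycle axis
#'
#' Linearly interpolates a raw sequence spanning exactly one gait cycle onto
#' 101 evenly spaced cycle positions (0..100%), preserving the endpoints.
#'
#' @param raw_samples Numeric vector of at least 8 finite samples covering one
#'   cycle.
#' @param parameter_name Name of the gait parameter the samples measure.
#' @param units Unit string (e.g. `"deg"`, `"W/kg"`).
#' @return A `gait_waveform`: list with `parameter_name`, `values` (length
#'   101), `cycle_axis` (0..100) and `units`.
#' @export
#' @examples
#' w <- normalize_cycle(sin(seq(0, 2 * pi, length.out = 120)), "knee_flexion_angle")
#' length(w$values)
normalize_cycle <- function(raw_samples, parameter_name = "unknown",
                            units = NA_character_) {
  if (!is.numeric(raw_samples) || length(raw_samples) < 8L)
    gw_validation_error("`raw_samples` must be numeric with length >= 8")
  if (!all(is.finite(raw_samples)))
    gw_validation_error("`raw_samples` contains non-finite values")
  x <- seq(0, 100, length.out = length(raw_samples))
  values <- if (length(raw_samples) == 101L) as.numeric(raw_samples)
            else approx(x, raw_samples, xout = GW_CYCLE_AXIS)$y
  gait_waveform(values, parameter_name, units)
}

#' Construct a gait waveform already on the 101-point axis
#' @param values Numeric vector of length 101.
#' @inheritParams normalize_cycle
#' @return A `gait_waveform`.
#' @export
gait_waveform <- function(values, parameter_name = "unknown",
                          units = NA_character_) {
  if (length(values) != 101L || !all(is.finite(values)))
    gw_validation_error("waveform `values` must be 101 finite samples")
  structure(list(parameter_name = parameter_name,
                 values = as.numeric(values),
                 cycle_axis = GW_CYCLE_AXIS,
                 units = units),
            class = "gait_waveform")
}

#' Default gait-cycle phase map
#'
#' Builds the stance/swing boundary and the seven named sub-phase windows.
#' Stance sub-phases occupy 1/6, 2/6, 2/6, 1/6 of `[0, toe_off_pct]`; swing is
#' split into equal thirds of `[toe_off_pct, 100]`. Windows are half-open
#' `[start, end)` with the final window closed at 100, so they partition the
#' cycle exactly.
#'
#' @param toe_off_pct Stance/swing boundary, percent of cycle in `[30, 80]`.
#' @return A `phase_map`: list with `toe_off_pct` and `subphases` (named list
#'   of `c(start, end)` windows).
#' @export
#' @examples
#' default_phase_map()$subphases$mid_stance
default_phase_map <- function(toe_off_pct = 60) {
  stopifnot_scalar_number(toe_off_pct, "toe_off_pct")
  if (toe_off_pct < 30 || toe_off_pct > 80)
    gw_validation_error("`toe_off_pct` must lie in [30, 80]")
  st <- toe_off_pct * cumsum(c(0, 1, 2, 2, 1)) / 6
  sw <- toe_off_pct + (100 - toe_off_pct) * (0:3) / 3
  bounds <- c(st, sw[-1])  # 0, .., toe_off, .., 100
  subphases <- lapply(seq_len(7), function(i) c(start = bounds[i], end = bounds[i + 1]))
  names(subphases) <- GW_SUBPHASES
  structure(list(toe_off_pct = toe_off_pct, subphases = subphases),
            class = "phase_map")
}

#' Resolve a window name to `(start, end)` on the cycle axis
#'
#' Accepts the seven sub-phase names, `"stance"`, `"swing"`, `"full"`, and the
#' compound window `"terminal_stance_pre_swing"` (union of the two adjacent
#' sub-phases).
#'
#' @param phase_map A `phase_map`.
#' @param window Window name.
#' @return Numeric `c(start, end)`.
#' @export
phase_window <- function(phase_map, window) {
  if (!inherits(phase_map, "phase_map"))
    gw_validation_error("`phase_map` must be a phase_map")
  sp <- phase_map$subphases
  switch(window,
    full   = c(start = 0, end = 100),
    stance = c(start = 0, end = phase_map$toe_off_pct),
    swing  = c(start = phase_map$toe_off_pct, end = 100),
    terminal_stance_pre_swing =
      c(start = sp$terminal_stance[["start"]], end = sp$pre_swing[["end"]]),
    {
      if (!window %in% names(sp))
        gw_validation_error(sprintf("unknown phase window '%s'", window))
      sp[[window]]
    })
}

# Integer cycle positions (0..100) falling in a window; half-open except that
# a window ending at 100 includes the final sample.
phase_window_idx <- function(phase_map, window) {
  w <- phase_window(phase_map, window)
  pos <- GW_CYCLE_AXIS
  keep <- pos >= w[["start"]] & (pos < w[["end"]] | (w[["end"]] == 100 & pos == 100))
  which(keep)  # 1-based indices into the 101-sample vector
}

#' Extract the samples of a waveform falling in a phase window
#'
#' @param waveform A `gait_waveform`.
#' @param window Window name (sub-phase, `"stance"`, `"swing"`, `"full"`, or
#'   `"terminal_stance_pre_swing"`).
#' @param phase_map A `phase_map` (default [default_phase_map()]).
#' @return Numeric vector of the samples whose cycle position lies in the
#'   window.
#' @export
slice_phase <- function(waveform, window, phase_map = default_phase_map()) {
  if (!inherits(waveform, "gait_waveform"))
    gw_validation_error("`waveform` must be a gait_waveform")
  idx <- phase_window_idx(phase_map, window)
  if (!length(idx))
    gw_error(sprintf("degenerate phase window '%s' produced an empty slice", window),
             "gw_internal_error")
  waveform$values[idx]
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("Gait phase map (toe-off %.1f%%)\n", x$toe_off_pct))
  for (nm in names(x$subphases))
    cat(sprintf("  %-18s [%6.2f, %6.2f)\n", nm,
                x$subphases[[nm]][["start"]], x$subphases[[nm]][["end"]]))
  invisible(x)
}
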