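# Feature operators on gait-cycle signals.
#
# Scalar user-facing functions raise a `gw_undefined_error` when a statistic
# is undefined (zero RMS for the crest factor, zero variance for kurtosis or
# autocorrelation). The matrix extraction path (extract.R) uses the same
# formulas column-wise and records undefined values in the missing mask
# instead of erroring.

GW_SUMMARY_STATS <- c("mean", "mean_abs", "sd", "sd_abs", "variance", "rms",
                      "peak2rms", "kurtosis", "max", "min", "max_minus_min")

#' Summary statistics of a signal segment
#'
#' Computes the eleven summary statistics used by the feature registry:
#' mean, mean of absolute value, standard deviation (n-1 denominator), SD of
#' the absolute value, variance, RMS, crest factor (`max(|x|)/rms`),
#' non-excess kurtosis (`m4/m2^2` with n-denominator moments, 3 for a
#' Gaussian), max, min, and range.
#'
#' @param x Numeric vector, length >= 2 (>= 4 for kurtosis).
#' @param stats Which statistics to return (default all eleven). A requested
#'   statistic that is undefined for `x` (zero RMS for `peak2rms`, zero
#'   variance or fewer than 4 samples for `kurtosis`) raises a
#'   `gw_undefined_error`; statistics not requested are not computed and
#'   cannot fail.
#' @return Named numeric vector of the requested statistics.
#' @export
#' @examples
#' summary_statistics(c(3, 4), stats = c("rms", "max_minus_min"))
summary_statistics <- function(x, stats = GW_SUMMARY_STATS) {
  if (!is.numeric(x) || length(x) < 2L || !all(is.finite(x)))
    gw_validation_error("`x` must be >= 2 finite numeric values")
  stats <- match.arg(stats, GW_SUMMARY_STATS, several.ok = TRUE)
  n <- length(x)
  m <- mean(x)
  xc <- x - m
  m2 <- mean(xc^2)
  rms <- sqrt(mean(x^2))
  if ("peak2rms" %in% stats && rms == 0)
    gw_undefined_error("peak2rms undefined: signal RMS is zero")
  if ("kurtosis" %in% stats) {
    if (m2 == 0)
      gw_undefined_error("kurtosis undefined: signal variance is zero")
    if (n < 4L)
      gw_undefined_error("kurtosis undefined for fewer than 4 samples")
  }
  out <- c(mean = m,
           mean_abs = mean(abs(x)),
           sd = sd(x),
           sd_abs = sd(abs(x)),
           variance = var(x),
           rms = rms,
           peak2rms = if (rms > 0) max(abs(x)) / rms else NA_real_,
           kurtosis = if (m2 > 0 && n >= 4L) mean(xc^4) / m2^2 else NA_real_,
           max = max(x),
           min = min(x),
           max_minus_min = max(x) - min(x))
  out[stats]
}

# trapezoid weights for a strictly increasing grid
trapz_weights <- function(pos) {
  n <- length(pos)
  if (n < 2L) gw_validation_error("need >= 2 positions for trapezoidal integration")
  d <- diff(pos)
  c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
}

#' Signed area under the curve within a phase window
#'
#' Trapezoidal integral of the waveform value against cycle percent over the
#' samples falling in the window (units: value x percent-of-cycle). Negative
#' values integrate negatively.
#'
#' @inheritParams slice_phase
#' @return Signed area (scalar).
#' @export
#' @examples
#' area_under_curve(gait_waveform(rep(2, 101)), "full")  # 200
area_under_curve <- function(waveform, window, phase_map = default_phase_map()) {
  if (!inherits(waveform, "gait_waveform"))
    gw_validation_error("`waveform` must be a gait_waveform")
  idx <- phase_window_idx(phase_map, window)
  if (length(idx) < 2L)
    gw_error(sprintf("window '%s' too narrow for integration", window),
             "gw_internal_error")
  pos <- waveform$cycle_axis[idx]
  sum(waveform$values[idx] * trapz_weights(pos))
}

#' Extremum of a waveform within a phase window
#'
#' @inheritParams slice_phase
#' @param which `"min"` or `"max"`.
#' @return The extremum of the sliced samples.
#' @export
phase_extremum <- function(waveform, window, which = c("min", "max"),
                           phase_map = default_phase_map()) {
  which <- match.arg(which)
  v <- slice_phase(waveform, window, phase_map)
  if (which == "min") min(v) else max(v)
}

# Periodogram machinery -------------------------------------------------------
#
# The cycle axis is sampled once per percent (interval 1%), so frequencies
# are in cycles per percent-of-cycle; the fundamental of a once-per-cycle
# oscillation is 0.01. The signal is demeaned before transforming. `psd_auc`
# is the trapezoidal integral of the two-sided periodogram density over one
# full period of the frequency axis; because the integrand is periodic the
# trapezoid rule is exact there and the area equals the population variance
# (Parseval). The occupied band is the smallest centred frequency interval of
# the one-sided spectrum containing `fraction` (default 99%) of total power,
# with sub-bin linear interpolation of the cumulative power.

#' Power-spectral-density features
#'
#' @param x Numeric vector, length >= 16 (the demeaned signal must not be all
#'   zero).
#' @param fraction Occupied-bandwidth power fraction, default 0.99.
#' @return Named list: `psd_auc` (equals the population variance by
#'   Parseval), `occupied_bandwidth`, `bandwidth_lower_bound`,
#'   `bandwidth_upper_bound` (frequencies in cycles per percent-of-cycle).
#' @export
psd_features <- function(x, fraction = 0.99) {
  if (!is.numeric(x) || length(x) < 16L || !all(is.finite(x)))
    gw_validation_error("`x` must be >= 16 finite numeric values")
  if (fraction <= 0 || fraction >= 1)
    gw_validation_error("`fraction` must lie in (0, 1)")
  n <- length(x)
  xc <- x - mean(x)
  if (all(xc == 0))
    gw_undefined_error("PSD undefined: signal is constant after mean removal")
  X <- fft(xc)
  df <- 1 / n                            # frequency bin width, cycles per %
  dens2 <- Mod(X)^2 / n                  # two-sided density at k/n, k=0..n-1
  # trapezoid over the periodically extended grid [0, 1]: exact by periodicity
  psd_auc <- sum(trapz_weights(seq(0, 1, by = df)) * c(dens2, dens2[1]))

  # one-sided power per bin
  kmax <- floor(n / 2)
  p <- dens2[seq_len(kmax + 1)] * df
  if (kmax >= 1) {
    two_sided <- 2:(kmax + 1)
    if (n %% 2 == 0) two_sided <- two_sided[-length(two_sided)]  # exact Nyquist
    p[two_sided] <- 2 * p[two_sided]
  }
  freq <- (0:kmax) * df
  tot <- sum(p)
  cum <- cumsum(p)
  tail_frac <- (1 - fraction) / 2
  interp_edge <- function(target) {
    k <- which(cum >= target)[1]
    prev <- if (k > 1) cum[k - 1] else 0
    # power of bin k spread uniformly over [freq_k - df/2, freq_k + df/2]
    lo <- freq[k] - df / 2
    max(0, lo + df * (target - prev) / p[k])
  }
  lower <- interp_edge(tail_frac * tot)
  upper <- interp_edge((1 - tail_frac) * tot)
  list(psd_auc = psd_auc,
       occupied_bandwidth = upper - lower,
       bandwidth_lower_bound = lower,
       bandwidth_upper_bound = upper)
}

#' Lower bound of the autocorrelation function
#'
#' Minimum over lags 1..n-1 of the biased, mean-removed, normalised
#' autocorrelation `r(k) = sum((x_t - xbar)(x_{t+k} - xbar)) / sum((x_t - xbar)^2)`.
#' Lag 0 (r = 1) is excluded from the minimum.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return The minimum autocorrelation value, in `[-1, 1]`.
#' @export
#' @examples
#' autocorr_lower_bound(c(1, -1))  # r(1) = -0.5
autocorr_lower_bound <- function(x) {
  if (!is.numeric(x) || length(x) < 2L || !all(is.finite(x)))
    gw_validation_error("`x` must be >= 2 finite numeric values")
  r <- acf_biased(x)
  if (is.null(r))
    gw_undefined_error("autocorrelation undefined: signal variance is zero")
  min(r)
}

# biased normalised ACF at lags 1..n-1, or NULL for zero variance
acf_biased <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(NULL)
  # FFT-based autocovariance (zero-padded circular convolution)
  nfft <- 2^ceiling(log2(2 * n))
  X <- fft(c(xc, rep(0, nfft - n)))
  ac <- Re(fft(X * Conj(X), inverse = TRUE)) / nfft
  ac[2:n] / denom
}

#' Mid-reference level of a bilevel signal
#'
#' Midpoint `(high + low) / 2` of the two state levels estimated by the
#' bimodal-histogram method: the signal range is split into `bins` equal
#' histogram bins; the low state is the centre of the most occupied bin in the
#' lower half of the range and the high state the most occupied bin in the
#' upper half. A constant signal returns the constant.
#'
#' @param x Numeric vector, length >= 8.
#' @param bins Number of histogram bins (default 100).
#' @return The mid-reference level.
#' @export
mid_reference_level <- function(x, bins = 100L) {
  if (!is.numeric(x) || length(x) < 8L || !all(is.finite(x)))
    gw_validation_error("`x` must be >= 8 finite numeric values")
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(lo)
  width <- (hi - lo) / bins
  idx <- pmin(bins, floor((x - lo) / width) + 1L)
  counts <- tabulate(idx, nbins = bins)
  half <- bins %/% 2
  low_bin <- which.max(counts[seq_len(half)])
  high_bin <- half + which.max(counts[(half + 1):bins])
  centre <- function(b) lo + (b - 0.5) * width
  (centre(low_bin) + centre(high_bin)) / 2
}

#' Dynamic time warping distance between two sequences
#'
#' Classic DTW with absolute-difference local cost (squared difference behind
#' the `cost` switch), unit step pattern `{(1,0),(0,1),(1,1)}`, boundary
#' alignment at both ends and no warping window. Returns the accumulated cost
#' of the optimal warping path.
#'
#' @param a,b Numeric sequences, each length >= 1.
#' @param cost `"absolute"` (default) or `"squared"` local cost.
#' @return Accumulated optimal-path cost (non-negative).
#' @export
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 3, 3))  # 0
dtw_distance <- function(a, b, cost = c("absolute", "squared")) {
  cost <- match.arg(cost)
  if (!is.numeric(a) || !is.numeric(b) || !length(a) || !length(b) ||
      !all(is.finite(a)) || !all(is.finite(b)))
    gw_validation_error("`a` and `b` must be non-empty finite numeric vectors")
  .dtw_cost_cpp(as.numeric(a), as.numeric(b), cost == "squared")
}

#' DTW distance between the stance and swing portions of a waveform
#'
#' Measures how dissimilar the stance-phase and swing-phase shapes of a gait
#' parameter are, allowing nonlinear time alignment between the two phases.
#'
#' @inheritParams slice_phase
#' @param cost Local cost, as in [dtw_distance()].
#' @return Accumulated DTW cost.
#' @export
dtw_stance_swing <- function(waveform, phase_map = default_phase_map(),
                             cost = "absolute") {
  a <- slice_phase(waveform, "stance", phase_map)
  b <- slice_phase(waveform, "swing", phase_map)
  if (length(a) < 2L || length(b) < 2L)
    gw_validation_error("stance and swing slices must each have >= 2 samples")
  dtw_distance(a, b, cost = cost)
}
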