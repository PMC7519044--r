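test_that("summary statistics match closed forms", {
  got <- summary_statistics(c(3, 4), stats = c("rms", "max_minus_min", "mean", "sd"))
  expect_equal(got[["rms"]], sqrt(12.5))
  expect_equal(got[["max_minus_min"]], 1)
  expect_equal(got[["sd"]], sd(c(3, 4)))

  alt <- rep(c(-1, 1), 50)
  s <- summary_statistics(alt)
  expect_equal(s[["kurtosis"]], 1)
  expect_equal(s[["rms"]], 1)
  expect_equal(s[["peak2rms"]], 1)
  expect_equal(s[["variance"]], var(alt))

  # constant non-zero signal: crest factor 1, kurtosis undefined
  expect_equal(summary_statistics(rep(7, 10), stats = "peak2rms")[["peak2rms"]], 1)
  expect_error(summary_statistics(rep(7, 10)), class = "gw_undefined_error")
  expect_error(summary_statistics(rep(0, 10), stats = "peak2rms"),
               class = "gw_undefined_error")
  expect_error(summary_statistics(c(1, 2, 3), stats = "kurtosis"),
               class = "gw_undefined_error")

  # n-1 denominators and moment formulas against base R on random input
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(37)
    s <- summary_statistics(x)
    expect_equal(s[["sd"]], sd(x))
    expect_equal(s[["variance"]], var(x))
    expect_equal(s[["sd_abs"]], sd(abs(x)))
    expect_equal(s[["rms"]], sqrt(mean(x^2)))
    expect_equal(s[["kurtosis"]], mean((x - mean(x))^4) / mean((x - mean(x))^2)^2)
  }
})

test_that("statistics obey their scale and shift invariances", {
  set.seed(11)
  x <- rnorm(101)
  for (c0 in c(-3, 0.5, 10)) {
    expect_equal(summary_statistics(c0 * x)[["peak2rms"]],
                 summary_statistics(x)[["peak2rms"]])
    expect_equal(summary_statistics(c0 * x)[["kurtosis"]],
                 summary_statistics(x)[["kurtosis"]])
    expect_equal(summary_statistics(c0 * x + 2)[["kurtosis"]],
                 summary_statistics(x)[["kurtosis"]])
    expect_equal(summary_statistics(c0 * x)[["rms"]],
                 abs(c0) * summary_statistics(x)[["rms"]])
    expect_equal(summary_statistics(c0 * x)[["sd"]],
                 abs(c0) * summary_statistics(x)[["sd"]])
    expect_equal(autocorr_lower_bound(c0 * x), autocorr_lower_bound(x))
    expect_equal(psd_features(c0 * x)$occupied_bandwidth,
                 psd_features(x)$occupied_bandwidth)
  }
})

test_that("area under the curve integrates signed values over the window", {
  pm <- default_phase_map(60)
  expect_equal(area_under_curve(gait_waveform(rep(2, 101)), "full", pm), 200)
  expect_equal(area_under_curve(gait_waveform(rep(1, 101)), "stance", pm), 59)
  set.seed(2)
  w <- gait_waveform(rnorm(101))
  wn <- gait_waveform(-w$values)
  for (win in c("full", "stance", "mid_swing"))
    expect_equal(area_under_curve(wn, win, pm),
                 -area_under_curve(w, win, pm))
})

test_that("phase extrema evaluate the sliced samples", {
  pm <- default_phase_map(60)
  ramp <- gait_waveform(0:100)
  expect_equal(phase_extremum(ramp, "terminal_swing", "max", pm), 100)
  expect_equal(phase_extremum(ramp, "loading_response", "min", pm), 0)
  sine <- gait_waveform(sin(2 * pi * (0:100) / 100))
  idx <- 11:30  # mid-stance positions 10..29
  expect_equal(phase_extremum(sine, "mid_stance", "min", pm),
               min(sine$values[idx]))
  expect_equal(phase_extremum(sine, "mid_stance", "max", pm),
               max(sine$values[idx]))
})

test_that("periodogram features satisfy Parseval and localise sinusoids", {
  # a pure sinusoid on a DFT bin occupies (essentially) one frequency bin
  n <- 101
  for (k in c(1, 3, 7)) {
    x <- sin(2 * pi * k * (0:(n - 1)) / n)
    ps <- psd_features(x)
    f0 <- k / n
    expect_lte(ps$bandwidth_lower_bound, f0)
    expect_gte(ps$bandwidth_upper_bound, f0)
    expect_lte(ps$occupied_bandwidth, 2 / n)
  }
  set.seed(9)
  x <- rnorm(101)
  expect_equal(psd_features(2 * x)$psd_auc, 4 * psd_features(x)$psd_auc)
  # Parseval: area equals the population variance
  for (i in 1:20) {
    y <- rnorm(101) + sin(2 * pi * runif(1, 1, 8) * (0:100) / 101)
    expect_equal(psd_features(y)$psd_auc, mean((y - mean(y))^2),
                 tolerance = 1e-6)
  }
  expect_error(psd_features(rep(5, 20)), class = "gw_undefined_error")
})

test_that("autocorrelation lower bound matches the direct-formula oracle", {
  expect_equal(autocorr_lower_bound(c(1, -1)), -0.5)
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(sample(20:101, 1)) + sin(2 * pi * 2 * seq(0, 1, length.out = 101))[1]
    r <- acf_brute(x)
    expect_equal(autocorr_lower_bound(x), min(r), tolerance = 1e-9)
    expect_gte(autocorr_lower_bound(x), -1)
    expect_lte(autocorr_lower_bound(x), 1)
  }
  x2 <- sin(2 * pi * 2 * (0:100) / 101)
  expect_equal(autocorr_lower_bound(x2), min(acf_brute(x2)), tolerance = 1e-9)
  expect_error(autocorr_lower_bound(rep(1, 50)), class = "gw_undefined_error")
})

test_that("mid-reference level finds the midpoint of the two state levels", {
  expect_equal(mid_reference_level(rep(c(0, 10), 25)), 5)
  expect_equal(mid_reference_level(rep(7.3, 20)), 7.3)
  set.seed(5)
  x <- rep(c(-3, 5), 50) + runif(100, -0.1, 0.1)
  expect_equal(mid_reference_level(x), 1.0, tolerance = 0.1)
})

test_that("DTW distance matches its optimal-alignment definition", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3, 3)), 0)
  expect_equal(dtw_distance(c(0, 0), c(1, 1)), 2)
  set.seed(21)
  for (i in 1:25) {
    a <- sample(0:3, sample(2:6, 1), replace = TRUE)
    b <- sample(0:3, sample(2:6, 1), replace = TRUE)
    expect_equal(dtw_distance(a, b), dtw_enum(a, b))
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))  # symmetric steps
    expect_gte(dtw_distance(a, b), 0)
  }
  # independent shortest-path formulation agrees
  for (i in 1:5) {
    a <- runif(6); b <- runif(5)
    expect_equal(dtw_distance(a, b), dtw_igraph(a, b), tolerance = 1e-12)
  }
  # squared-cost switch
  expect_equal(dtw_distance(c(0, 0), c(2, 2), cost = "squared"), 8)
})

test_that("stance-vs-swing DTW is zero for self-similar phases", {
  pm <- default_phase_map(60)
  # stance (0..59) and swing (60..100) identical constant: distance 0
  expect_equal(dtw_stance_swing(gait_waveform(rep(1, 101)), pm), 0)
  set.seed(3)
  w <- gait_waveform(rnorm(101))
  expect_equal(dtw_stance_swing(w, pm),
               dtw_distance(slice_phase(w, "stance", pm),
                            slice_phase(w, "swing", pm)))
})
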