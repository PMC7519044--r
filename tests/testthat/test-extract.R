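test_that("registries have the declared sizes and unique ids", {
  full <- build_feature_registry("full")
  expect_gte(nrow(full), 1000)
  expect_false(anyDuplicated(full$feature_id) > 0)
  t2 <- build_feature_registry("table2")
  expect_equal(nrow(t2), 42)
  expect_true(all(t2$feature_id %in% full$feature_id |
                    t2$operator %in% c("value")))
  # every table2 parameter is registered
  expect_true(all(t2$parameter %in% c(gait_parameters()$parameter,
                                      spatiotemporal_parameters()$parameter)))
})

test_that("extraction is deterministic and matches the declared registry", {
  cohort <- tiny_cohort()
  reg <- build_feature_registry("full")
  fm1 <- extract_features(cohort, reg)
  fm2 <- extract_features(cohort, reg)
  expect_identical(fm1$values, fm2$values)   # bit-identical
  expect_equal(dim(fm1$values), c(cohort_size(cohort), nrow(reg)))
  expect_identical(colnames(fm1$values), reg$feature_id)
})

test_that("single-trial extraction agrees with the matrix path", {
  cohort <- tiny_cohort()
  reg <- build_feature_registry("table2")
  fm <- extract_features(cohort, reg)
  trial <- get_trial(cohort, 5)
  row <- extract_all(trial, reg)
  expect_equal(as.numeric(row), unname(fm$values[5, ]))
  expect_length(row, 42)
  expect_false(any(attr(row, "mask")))
  expect_length(extract_all(trial, reg[0, ]), 0)
})

test_that("matrix extraction reproduces the scalar operators slice by slice", {
  cohort <- tiny_cohort()
  reg <- build_feature_registry("full")
  fm <- extract_features(cohort, reg)
  pm <- cohort$phase_map
  j <- 7  # arbitrary subject
  w <- get_trial(cohort, j)$waveforms$knee_varus_angle
  pick <- function(id) fm$values[j, id]
  expect_equal(pick("knee_varus_angle.auc.stance"),
               area_under_curve(w, "stance", pm))
  expect_equal(pick("knee_varus_angle.max.mid_stance"),
               phase_extremum(w, "mid_stance", "max", pm))
  expect_equal(pick("knee_varus_angle.rms"),
               summary_statistics(w$values)[["rms"]])
  expect_equal(pick("knee_varus_angle.kurtosis.swing"),
               summary_statistics(slice_phase(w, "swing", pm))[["kurtosis"]])
  expect_equal(pick("knee_varus_angle.sd.pre_swing"),
               sd(slice_phase(w, "pre_swing", pm)))
  expect_equal(pick("knee_varus_angle.psd_auc"),
               psd_features(w$values)$psd_auc)
  expect_equal(pick("knee_varus_angle.occupied_bandwidth"),
               psd_features(w$values)$occupied_bandwidth)
  expect_equal(pick("knee_varus_angle.autocorr_lower_bound"),
               autocorr_lower_bound(w$values))
  expect_equal(pick("knee_varus_angle.mid_reference_level"),
               mid_reference_level(w$values))
  expect_equal(pick("knee_varus_angle.dtw_stance_swing"),
               dtw_stance_swing(w, pm))
  expect_equal(pick("total_speed.value"),
               unname(get_trial(cohort, j)$spatiotemporal["total_speed"]))
})

test_that("unknown parameters are rejected and undefined statistics masked", {
  cohort <- tiny_cohort()
  bogus <- data.frame(feature_id = "elbow_angle.mean", parameter = "elbow_angle",
                      operator = "mean", window = "full", units = "deg",
                      stringsAsFactors = FALSE)
  expect_error(extract_features(cohort, bogus), class = "gw_validation_error")

  # a constant waveform leaves kurtosis/peak2rms undefined -> masked, dropped
  n <- 4L
  wf <- list(knee_varus_angle = matrix(5, 101, n))
  womac <- data.frame(subject_id = paste0("T", 1:n),
                      matrix(0L, n, 24, dimnames = list(NULL, sprintf("item_%02d", 1:24))))
  names(womac) <- c("subject_id", sprintf("item_%02d", 1:24))
  co <- gait_cohort(paste0("T", 1:n), wf,
                    data.frame(total_speed = rep(80, n)), womac)
  reg <- data.frame(feature_id = c("knee_varus_angle.kurtosis", "knee_varus_angle.mean"),
                    parameter = "knee_varus_angle",
                    operator = c("kurtosis", "mean"), window = "full",
                    units = "deg", stringsAsFactors = FALSE)
  fm <- extract_features(co, reg)
  expect_true(all(fm$mask[, "knee_varus_angle.kurtosis"]))
  expect_equal(unname(fm$values[, "knee_varus_angle.mean"]), rep(5, n))
  expect_message(fmc <- drop_masked_features(fm), "dropping 1 feature")
  expect_equal(ncol(fmc$values), 1L)
})
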