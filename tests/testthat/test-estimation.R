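test_that("greedy largest-class trimming reproduces the balanced split", {
  expect_equal(balanced_group_sizes(c(140L, 182L, 53L), 231L), c(89L, 89L, 53L))
  expect_equal(balanced_group_sizes(c(10L, 10L, 10L), 30L), c(10L, 10L, 10L))
  expect_equal(sum(balanced_group_sizes(c(140L, 182L, 53L), 231L)), 231L)
  expect_error(balanced_group_sizes(c(5L, 5L), 1L), class = "gw_validation_error")
  expect_error(balanced_group_sizes(c(5L, 5L), 20L), class = "gw_validation_error")
})

test_that("down-sampling removes subjects only from the largest classes", {
  set.seed(1)
  ids <- sprintf("S%03d", 1:375)
  cls <- factor(rep(severity_levels(), times = c(140, 182, 53)),
                levels = severity_levels(), ordered = TRUE)
  keep <- balance_downsample(ids, cls, 231L, seed = 4L)
  kept_cls <- cls[match(keep, ids)]
  expect_equal(as.integer(table(kept_cls)), c(89L, 89L, 53L))
  # minority class intact
  expect_true(all(ids[cls == "severe"] %in% keep))
  # deterministic given the seed; identity when target covers the cohort
  expect_identical(keep, balance_downsample(ids, cls, 231L, seed = 4L))
  expect_false(identical(keep, balance_downsample(ids, cls, 231L, seed = 5L)))
  expect_identical(balance_downsample(ids, cls, 375L, seed = 1L), ids)
})

test_that("the hold-out split is a stratified exact partition", {
  ids <- sprintf("S%03d", 1:231)
  cls <- factor(rep(severity_levels(), times = c(89, 89, 53)),
                levels = severity_levels(), ordered = TRUE)
  sp <- holdout_split(ids, cls, 0.7, seed = 2L)
  expect_length(sp$train, 162)
  expect_length(sp$test, 69)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  # all classes on both sides
  expect_true(all(table(cls[match(sp$train, ids)]) > 0))
  expect_true(all(table(cls[match(sp$test, ids)]) > 0))
  sp2 <- holdout_split(sprintf("x%d", 1:10), train_fraction = 0.5, seed = 1L,
                       stratify = FALSE)
  expect_length(sp2$train, 5)
  expect_length(sp2$test, 5)
  expect_error(holdout_split(ids, cls, 1.2), class = "gw_validation_error")
})

make_fm <- function(X, ids) {
  reg <- data.frame(feature_id = colnames(X), parameter = colnames(X),
                    operator = "value", window = "full", units = "1",
                    stringsAsFactors = FALSE)
  structure(list(subject_ids = ids, registry = reg, values = X,
                 mask = is.na(X)), class = "feature_matrix")
}

test_that("linear regression recovers exact and noisy coefficients", {
  set.seed(6)
  n <- 200
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  ids <- sprintf("S%03d", 1:n)
  fm <- make_fm(X, ids)
  split <- holdout_split(ids, train_fraction = 0.7, seed = 3L, stratify = FALSE)

  y_exact <- 2 + 3 * X[, 1] - 1.5 * X[, 2]
  lin <- fit_linear(fm, y_exact, c("x1", "x2"), split$train, split$test)
  co <- setNames(lin$coefficients$estimate, lin$coefficients$term)
  expect_equal(unname(co[c("(Intercept)", "x1", "x2")]), c(2, 3, -1.5),
               tolerance = 1e-8)
  expect_lt(lin$rmse, 1e-8)

  # y = 3 x1 + noise(sd 1): slope near 3, hold-out r near 3/sqrt(10)
  y <- 3 * X[, 1] + rnorm(n)
  lin2 <- fit_linear(fm, y, "x1", split$train, split$test)
  co2 <- setNames(lin2$coefficients$estimate, lin2$coefficients$term)
  expect_equal(unname(co2["x1"]), 3, tolerance = 0.3)
  rs <- vapply(1:30, function(s) {
    yy <- 3 * X[, 1] + rnorm(n)
    fit_linear(fm, yy, "x1", split$train, split$test)$pearson_r
  }, numeric(1))
  expect_equal(mean(rs), 3 / sqrt(10), tolerance = 0.05)

  # permuted responses: hold-out correlation centred on zero
  rp <- vapply(1:40, function(s) {
    fit_linear(fm, sample(y), "x1", split$train, split$test)$pearson_r
  }, numeric(1))
  expect_lt(abs(mean(rp)), 0.08)
})

test_that("rank-deficient designs fail loudly unless allowed", {
  set.seed(77)
  n <- 60
  X <- cbind(a = rnorm(n), b = rnorm(n))
  X <- cbind(X, c = X[, "a"] * 2)   # exact collinearity
  ids <- sprintf("S%02d", 1:n)
  fm <- make_fm(X, ids)
  split <- holdout_split(ids, train_fraction = 0.7, seed = 1L, stratify = FALSE)
  y <- X[, "a"] + rnorm(n)
  expect_error(fit_linear(fm, y, c("a", "b", "c"), split$train, split$test),
               "collinear column", class = "gw_validation_error")
  expect_message(
    lin <- fit_linear(fm, y, c("a", "b", "c"), split$train, split$test,
                      allow_rank_deficient = TRUE),
    "aliased")
  expect_true(is.finite(lin$rmse))
  # more features than training rows is refused
  Xbig <- matrix(rnorm(12 * 20), 12, 20,
                 dimnames = list(NULL, paste0("v", 1:20)))
  fm_big <- make_fm(Xbig, sprintf("A%d", 1:12))
  expect_error(fit_linear(fm_big, rnorm(12), paste0("v", 1:20),
                          sprintf("A%d", 1:6), sprintf("A%d", 7:12)),
               class = "gw_validation_error")
})

test_that("random forest regression is seeded and learns simple structure", {
  set.seed(14)
  n <- 150
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  ids <- sprintf("S%03d", 1:n)
  fm <- make_fm(X, ids)
  split <- holdout_split(ids, train_fraction = 0.7, seed = 2L, stratify = FALSE)
  y <- ifelse(X[, 1] > 0, 10, 0) + rnorm(n, 0, 0.5)
  rf1 <- fit_random_forest(fm, y, c("x1", "x2"), split$train, split$test,
                           ntree = 200L, seed = 9L)
  rf2 <- fit_random_forest(fm, y, c("x1", "x2"), split$train, split$test,
                           ntree = 200L, seed = 9L)
  expect_identical(rf1$predictions$predicted, rf2$predictions$predicted)
  expect_lt(rf1$rmse, sd(y))            # learns the step
  expect_equal(rf1$hyperparameters$nodesize, 5L)

  # constant response: constant predictions with zero error (the forest and
  # the correlation both warn about the degenerate response)
  rfc <- suppressWarnings(
    fit_random_forest(fm, rep(42, n), c("x1", "x2"),
                      split$train, split$test, ntree = 50L, seed = 1L))
  expect_equal(rfc$rmse, 0)
  expect_true(all(rfc$predictions$predicted == 42))
})

test_that("hold-out metrics match their definitions", {
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$rmse, 0)
  expect_equal(ev$pearson_r, 1)
  ev2 <- evaluate_predictions(c(6, 7, 8), c(1, 2, 3))
  expect_equal(ev2$rmse, 5)
  expect_equal(ev2$pearson_r, 1)
  ev3 <- evaluate_predictions(c(0, 10, 26), c(0, 10, 20))
  expect_equal(ev3$rmse, sqrt(12))
  expect_equal(ev3$pearson_r, 130 / sqrt(172 * 100))   # 0.99123
  expect_equal(ev3$pearson_r, cor(c(0, 10, 26), c(0, 10, 20)))
  # constant actuals: correlation undefined, RMSE still returned
  expect_warning(ev4 <- evaluate_predictions(c(1, 2, 3), c(5, 5, 5)),
                 class = "gw_undefined_warning")
  expect_true(is.na(ev4$pearson_r))
  expect_equal(ev4$rmse, sqrt(mean(c(16, 9, 4))))
  expect_error(evaluate_predictions(1:3, 1:4), class = "gw_validation_error")
})
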