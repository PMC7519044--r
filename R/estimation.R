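# WOMAC estimation: class balancing, hold-out split, linear and random-forest
# regression, and hold-out metrics.

#' Balanced group sizes after greedy largest-class trimming
#'
#' Deterministic arithmetic of the class-balancing down-sample: the current
#' largest class loses one subject at a time until the total reaches
#' `target_total`. Starting from (140, 182, 53) with target 231 this yields
#' (89, 89, 53): imbalance is removed from the majority classes while the
#' minority class is kept intact.
#'
#' @param sizes Integer class sizes.
#' @param target_total Desired total (default 231).
#' @return Integer vector of trimmed sizes (same order as `sizes`).
#' @export
balanced_group_sizes <- function(sizes, target_total = 231L) {
  sizes <- as.integer(sizes)
  if (target_total < length(sizes))
    gw_validation_error("`target_total` must keep at least one subject per class")
  if (target_total > sum(sizes))
    gw_validation_error("`target_total` exceeds the cohort size")
  while (sum(sizes) > target_total) {
    i <- which.max(sizes)
    sizes[i] <- sizes[i] - 1L
  }
  sizes
}

#' Random under-sampling of the largest severity classes
#'
#' Removes randomly chosen subjects from whichever class is currently largest
#' until the total equals `target_total`; deterministic given the seed.
#'
#' @param subject_ids Character vector of subject ids.
#' @param classes Severity factor aligned with `subject_ids`.
#' @param target_total Total after balancing (default 231; clipped to the
#'   cohort size if the cohort is smaller).
#' @param seed Integer seed.
#' @return Character vector of the retained subject ids (in original order).
#' @export
balance_downsample <- function(subject_ids, classes, target_total = 231L,
                               seed = 1L) {
  classes <- droplevels(factor(classes))
  if (length(subject_ids) != length(classes))
    gw_validation_error("`subject_ids` and `classes` must be aligned")
  k <- nlevels(classes)
  if (target_total < k)
    gw_validation_error("`target_total` too small to keep all classes")
  if (target_total >= length(subject_ids)) return(subject_ids)
  sizes <- as.integer(table(classes))
  keep_sizes <- balanced_group_sizes(sizes, target_total)
  set.seed(seed)
  keep <- logical(length(subject_ids))
  for (g in seq_len(k)) {
    members <- which(classes == levels(classes)[g])
    keep[sample(members, keep_sizes[g])] <- TRUE
  }
  subject_ids[keep]
}

#' Stratified hold-out split
#'
#' Random partition into training and validation sets with overall train size
#' `round(train_fraction * n)`. With stratification (default) the per-class
#' train counts are floors plus largest-remainder top-ups, so every class is
#' represented on both sides and the overall count is met exactly.
#'
#' @param subject_ids Character vector of subject ids.
#' @param classes Severity factor (used when `stratify = TRUE`).
#' @param train_fraction Fraction of subjects used for training (default 0.7).
#' @param seed Integer seed.
#' @param stratify Stratify by severity class (default `TRUE`).
#' @return List with `train` and `test` id vectors (disjoint; union is the
#'   input).
#' @export
holdout_split <- function(subject_ids, classes = NULL, train_fraction = 0.7,
                          seed = 1L, stratify = TRUE) {
  n <- length(subject_ids)
  if (train_fraction <= 0 || train_fraction >= 1)
    gw_validation_error("`train_fraction` must lie in (0, 1)")
  if (n < 10L)
    gw_validation_error("need >= 10 subjects to split")
  n_train <- round(train_fraction * n)
  set.seed(seed)
  if (stratify && !is.null(classes)) {
    classes <- droplevels(factor(classes))
    idx_train <- integer(0)
    raw <- train_fraction * as.integer(table(classes))
    base <- floor(raw)
    topup <- order(raw - base, decreasing = TRUE)
    extra <- n_train - sum(base)
    if (extra > 0) base[topup[seq_len(extra)]] <- base[topup[seq_len(extra)]] + 1L
    if (extra < 0) {
      shrink <- order(raw - floor(raw))
      base[shrink[seq_len(-extra)]] <- base[shrink[seq_len(-extra)]] - 1L
    }
    for (g in seq_len(nlevels(classes))) {
      members <- which(classes == levels(classes)[g])
      idx_train <- c(idx_train, sample(members, base[g]))
    }
  } else {
    idx_train <- sample.int(n, n_train)
    if (!is.null(classes)) {
      tr <- table(factor(classes[idx_train]))
      te <- table(factor(classes[-idx_train]))
      if (any(tr == 0) || any(te == 0))
        warning("a severity class is absent from one side of the split")
    }
  }
  list(train = subject_ids[sort(idx_train)],
       test = subject_ids[sort(setdiff(seq_len(n), idx_train))])
}

#' Hold-out metrics
#'
#' @param predictions,actual Numeric vectors of equal length >= 3.
#' @return List with `rmse` (same units as the score) and `pearson_r`.
#'   Constant actuals leave the correlation undefined: `pearson_r` is `NA`
#'   with a `gw_undefined_warning`; the RMSE is still returned.
#' @export
#' @examples
#' evaluate_predictions(c(0, 10, 26), c(0, 10, 20))
evaluate_predictions <- function(predictions, actual) {
  if (length(predictions) != length(actual) || length(actual) < 3L)
    gw_validation_error("predictions and actuals must be aligned, length >= 3")
  rmse <- sqrt(mean((predictions - actual)^2))
  r <- if (var(actual) == 0 || var(predictions) == 0) {
    warning(structure(class = c("gw_undefined_warning", "warning", "condition"),
                      list(message = "pearson_r undefined: constant input",
                           call = sys.call(-1))))
    NA_real_
  } else cor(predictions, actual)
  list(rmse = rmse, pearson_r = r)
}

new_model_report <- function(kind, feature_ids, y_train, fit_train, fit_test,
                             ids_train, ids_test, pred_train, pred_test,
                             hyper, seed, coefficients = NULL) {
  structure(list(
    model_kind = kind,
    feature_ids = feature_ids,
    n_train = length(pred_train), n_test = length(pred_test),
    rmse = fit_test$rmse, pearson_r = fit_test$pearson_r,
    rmse_train = fit_train$rmse, pearson_r_train = fit_train$pearson_r,
    seed = seed, hyperparameters = hyper,
    coefficients = coefficients,
    predictions = data.frame(
      subject_id = c(ids_train, ids_test),
      actual = c(y_train$train, y_train$test),
      predicted = c(pred_train, pred_test),
      split = rep(c("train", "test"), c(length(pred_train), length(pred_test))),
      stringsAsFactors = FALSE)),
    class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("%s model: train n=%d, test n=%d\n  hold-out RMSE %.3f, Pearson r %.3f (train RMSE %.3f, r %.3f)\n",
              x$model_kind, x$n_train, x$n_test, x$rmse, x$pearson_r,
              x$rmse_train, x$pearson_r_train))
  invisible(x)
}

prepare_xy <- function(fm, totals, key_features, train_ids, test_ids) {
  X <- fm$values[, key_features, drop = FALSE]
  if (anyNA(X))
    gw_validation_error("model features contain masked values")
  it <- match(train_ids, fm$subject_ids)
  iv <- match(test_ids, fm$subject_ids)
  if (anyNA(it) || anyNA(iv))
    gw_validation_error("split ids not found in the feature matrix")
  list(Xtr = X[it, , drop = FALSE], Xte = X[iv, , drop = FALSE],
       ytr = totals[it], yte = totals[iv])
}

#' Multiple linear regression of the WOMAC total on key features
#'
#' Ordinary least squares with intercept. A rank-deficient design raises an
#' error naming the collinear columns unless `allow_rank_deficient = TRUE`, in
#' which case the aliased columns are dropped (with a message).
#'
#' @param fm A `feature_matrix` covering train and test subjects.
#' @param totals Numeric WOMAC totals aligned with `fm$subject_ids`.
#' @param key_features Feature ids to use as predictors.
#' @param train_ids,test_ids Subject ids of the split.
#' @param allow_rank_deficient Drop aliased columns instead of failing.
#' @return A `model_report` with hold-out and in-sample metrics and the
#'   coefficient table.
#' @export
fit_linear <- function(fm, totals, key_features, train_ids, test_ids,
                       allow_rank_deficient = FALSE) {
  d <- prepare_xy(fm, totals, key_features, train_ids, test_ids)
  if (nrow(d$Xtr) <= ncol(d$Xtr))
    gw_validation_error("more features than training subjects; reduce the feature set")
  Ztr <- cbind(`(Intercept)` = 1, d$Xtr)
  fit <- stats::lm.fit(Ztr, d$ytr)
  aliased <- colnames(Ztr)[is.na(fit$coefficients)]
  if (length(aliased)) {
    if (!allow_rank_deficient)
      gw_validation_error(sprintf(
        "rank-deficient design; collinear column(s): %s",
        paste(aliased, collapse = ", ")))
    message(sprintf("dropping %d aliased column(s)", length(aliased)))
  }
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  pred_tr <- drop(Ztr %*% beta)
  pred_te <- drop(cbind(1, d$Xte) %*% beta)
  new_model_report(
    "linear", key_features,
    list(train = d$ytr, test = d$yte),
    evaluate_predictions(pred_tr, d$ytr),
    evaluate_predictions(pred_te, d$yte),
    train_ids, test_ids, pred_tr, pred_te,
    hyper = list(intercept = TRUE, rank = fit$rank),
    seed = NA_integer_,
    coefficients = data.frame(term = names(beta), estimate = unname(beta),
                              stringsAsFactors = FALSE))
}

#' Random-forest regression of the WOMAC total on key features
#'
#' Bagged regression trees with feature subsampling via the randomForest
#' package. Defaults: 500 trees, one third of the features tried per split,
#' unlimited depth, minimum node size 5; seeded and reproducible.
#'
#' @inheritParams fit_linear
#' @param ntree,mtry,nodesize Forest hyperparameters (`mtry` defaults to
#'   `max(1, floor(p / 3))`).
#' @param seed Integer seed.
#' @return A `model_report`.
#' @export
fit_random_forest <- function(fm, totals, key_features, train_ids, test_ids,
                              ntree = 500L, mtry = NULL, nodesize = 5L,
                              seed = 1L) {
  d <- prepare_xy(fm, totals, key_features, train_ids, test_ids)
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(d$Xtr) / 3))
  set.seed(seed)
  rf <- randomForest::randomForest(x = d$Xtr, y = d$ytr, ntree = ntree,
                                   mtry = mtry, nodesize = nodesize)
  pred_tr <- unname(predict(rf, d$Xtr))
  pred_te <- unname(predict(rf, d$Xte))
  new_model_report(
    "random_forest", key_features,
    list(train = d$ytr, test = d$yte),
    evaluate_predictions(pred_tr, d$ytr),
    evaluate_predictions(pred_te, d$yte),
    train_ids, test_ids, pred_tr, pred_te,
    hyper = list(ntree = ntree, mtry = mtry, nodesize = nodesize),
    seed = seed)
}
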