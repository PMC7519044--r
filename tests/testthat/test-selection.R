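test_that("the ANOVA screen matches hand-computed sums of squares", {
  X <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), ncol = 1)
  cls <- factor(rep(c("mild", "moderate", "severe"), each = 3),
                levels = severity_levels(), ordered = TRUE)
  res <- gaitwomac:::column_anova(X, cls)
  expect_equal(res$F, 3)                        # SSB 6 / 2 over SSW 6 / 6
  expect_equal(res$p, pf(3, 2, 6, lower.tail = FALSE))

  # three identical groups: F = 0, never significant
  X0 <- matrix(rep(c(1, 5, 9), 3), ncol = 1)
  expect_equal(gaitwomac:::column_anova(X0, cls)$F, 0)

  # all-constant column: statistic undefined, not passed
  fm_like <- cbind(a = c(1, 2, 3, 2, 3, 4, 3, 4, 5), b = rep(2, 9))
  scr <- anova_screen(fm_like, cls, alpha = 0.5)
  expect_true(is.na(scr$p[scr$feature_id == "b"]))
  expect_false(scr$passed[scr$feature_id == "b"])
})

test_that("vectorised tests agree with stats::oneway.test and stats::t.test", {
  set.seed(8)
  n <- 45
  cls <- factor(rep(severity_levels(), times = c(20, 15, 10)),
                levels = severity_levels(), ordered = TRUE)
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("f", 1:12)))
  res <- gaitwomac:::column_anova(X, cls)
  for (j in 1:12) {
    ow <- oneway.test(X[, j] ~ cls, var.equal = TRUE)
    expect_equal(unname(res$F[j]), unname(ow$statistic), tolerance = 1e-12)
    expect_equal(unname(res$p[j]), unname(ow$p.value), tolerance = 1e-12)
  }
  tt <- gaitwomac:::column_ttest(X, cls == "mild", cls == "severe")
  for (j in 1:12) {
    bt <- t.test(X[cls == "mild", j], X[cls == "severe", j], var.equal = TRUE)
    expect_equal(unname(tt$t[j]), unname(bt$statistic), tolerance = 1e-12)
    expect_equal(unname(tt$p[j]), unname(bt$p.value), tolerance = 1e-12)
  }
  # Welch variant against t.test default
  tw <- gaitwomac:::column_ttest(X, cls == "mild", cls == "severe", welch = TRUE)
  bw <- t.test(X[cls == "mild", 3], X[cls == "severe", 3])
  expect_equal(unname(tw$p[3]), unname(bw$p.value), tolerance = 1e-12)
})

test_that("pairwise t gate matches the pooled-variance hand computation", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  tt <- gaitwomac:::column_ttest(X, 1:3, 4:6)
  # pooled variance 1, so t = (2 - 5) / sqrt(2/3)
  expect_equal(tt$t, (2 - 5) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(tt$t, 3), -3.674)
  expect_equal(tt$p, 0.0213, tolerance = 1e-3)
  expect_equal(tt$df, 4)

  # clearly separated normal samples are detected far below the gate
  set.seed(12)
  Y <- matrix(c(rnorm(50, 0), rnorm(50, 5)), ncol = 1)
  t2 <- gaitwomac:::column_ttest(Y, 1:50, 51:100)
  expect_lt(t2$p, 1e-10)

  # identical groups: p = 1; zero-variance pair undefined
  Z <- cbind(x = c(1, 2, 3, 1, 2, 3), const = rep(3, 6))
  t3 <- gaitwomac:::column_ttest(Z, 1:3, 4:6)
  expect_lt(abs(unname(t3$t[1])), 1e-12)
  expect_equal(unname(t3$p[1]), 1)
  expect_true(is.na(t3$p[2]))
})

test_that("the F statistic reduces to the squared t for two groups", {
  set.seed(30)
  X <- matrix(rnorm(40 * 5), 40, 5)
  cls2 <- factor(rep(c("a", "b"), each = 20))
  Fres <- gaitwomac:::column_anova(X, cls2)
  tres <- gaitwomac:::column_ttest(X, cls2 == "a", cls2 == "b")
  expect_equal(Fres$F, tres$t^2, tolerance = 1e-12)
})

test_that("key features require both gates and are ordered by ANOVA p", {
  co <- tiny_cohort()
  cls <- classify_scale_scores(cohort_womac_totals(co))
  fm <- suppressMessages(drop_masked_features(
    extract_features(co, build_feature_registry("table2"))))
  sel <- select_features(fm, cls)
  keys <- select_key_features(sel)
  tab <- sel$table
  expect_true(all(tab$key_feature == (tab$passed & tab$passed_all_pairs)))
  expect_identical(keys, tab$feature_id[tab$key_feature][
    order(tab$p[tab$key_feature], tab$feature_id[tab$key_feature])])
  # pairwise p-values only computed behind the ANOVA gate
  expect_true(all(is.na(tab$p_mild_moderate[!tab$passed])))

  # tightening either alpha never enlarges the selected set
  sel2 <- select_features(fm, cls, alpha_anova = 1e-6, alpha_pairwise = 3e-7)
  expect_true(all(select_key_features(sel2) %in% keys))
  sel3 <- select_features(fm, cls, bonferroni = "exact")
  expect_equal(sel3$alpha_pairwise, 1e-4 / 3)
  expect_true(all(select_key_features(sel3) %in% keys))
})

test_that("permuted class labels yield empty key sets at the configured alphas", {
  co <- tiny_cohort()
  cls <- classify_scale_scores(cohort_womac_totals(co))
  fm <- suppressMessages(drop_masked_features(
    extract_features(co, build_feature_registry("table2"))))
  set.seed(99)
  empty <- vapply(1:200, function(i) {
    length(select_key_features(select_features(fm, sample(cls)))) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.95)
})

test_that("subscale association returns nested subsets of the key set", {
  co <- tiny_cohort()
  cls <- classify_scale_scores(cohort_womac_totals(co))
  fm <- suppressMessages(drop_masked_features(
    extract_features(co, build_feature_registry("table2"))))
  keys <- select_key_features(select_features(fm, cls))
  subs <- subscale_association(fm, co$womac, keys)
  expect_named(subs, c("pain", "stiffness", "physical_function"))
  for (s in subs)
    if (!is.null(s)) expect_true(all(s %in% keys))

  # a degenerate subscale (all zeros) is flagged unevaluable
  womac0 <- co$womac
  womac0[, sprintf("item_%02d", 6:7)] <- 0L
  expect_warning(subs0 <- subscale_association(fm, womac0, keys),
                 "stiffness")
  expect_null(subs0$stiffness)
  expect_false(is.null(subs0$pain))
})

test_that("selection validates its inputs", {
  fm <- matrix(rnorm(20), 10, 2)
  cls <- factor(rep(c("mild", "moderate", "severe"), length.out = 10),
                levels = severity_levels(), ordered = TRUE)
  expect_error(anova_screen(cbind(fm, NA), cls), class = "gw_validation_error")
  expect_error(anova_screen(fm, cls[1:5]), class = "gw_validation_error")
  one_each <- factor(c("mild", "moderate", rep("severe", 8)),
                     levels = severity_levels())
  expect_error(anova_screen(fm, one_each), class = "gw_validation_error")
})
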