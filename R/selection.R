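# Feature selection: ANOVA screen, Bonferroni-corrected pairwise t-tests,
# key-feature intersection, and subscale association.
#
# The screen is a classical one-way fixed-effects ANOVA per feature at
# alpha = 0.0001; features passing it get all three pairwise two-sample
# Student (pooled-variance) t-tests at the Bonferroni-corrected alpha, printed
# as 0.00003 in the source analysis (0.0001 / 3 is available behind
# `bonferroni = "exact"`). Key features pass all gates. Statistics are
# computed by vectorised column-wise sums of squares; they agree with
# stats::oneway.test(var.equal = TRUE) and stats::t.test(var.equal = TRUE)
# column by column (asserted in the test suite).

GW_ALPHA_ANOVA <- 1e-4
GW_ALPHA_PAIRWISE <- 3e-5

# column-wise one-way ANOVA; X is n x p, classes a factor
column_anova <- function(X, classes) {
  classes <- droplevels(factor(classes))
  k <- nlevels(classes)
  n <- nrow(X)
  ns <- tabulate(classes, nbins = k)
  G <- model_group_means(X, classes)          # k x p
  grand <- colMeans(X)
  ssb <- colSums(ns * (G - matrix(grand, k, ncol(X), byrow = TRUE))^2)
  sst <- colSums(X^2) - n * grand^2
  ssw <- sst - ssb
  ssw[ssw < 0] <- 0
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  # an all-constant column has ssb = ssw = 0: the statistic is undefined
  Fstat[ssb == 0 & ssw == 0] <- NA_real_
  p <- pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  list(F = Fstat, p = p)
}

model_group_means <- function(X, classes) {
  k <- nlevels(classes)
  G <- matrix(0, k, ncol(X))
  for (g in seq_len(k))
    G[g, ] <- colMeans(X[classes == levels(classes)[g], , drop = FALSE])
  G
}

# column-wise pooled-variance two-sample t-test (two-sided); Welch behind flag
column_ttest <- function(X, in1, in2, welch = FALSE) {
  X1 <- X[in1, , drop = FALSE]; X2 <- X[in2, , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- (colSums(X1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(X2^2) - n2 * m2^2) / (n2 - 1)
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tstat[!is.finite(tstat)] <- NA_real_   # zero pooled variance -> undefined
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  list(t = tstat, p = p, df = df)
}

#' ANOVA screen across the three severity groups
#'
#' Classical one-way fixed-effects ANOVA per feature column.
#'
#' @param fm A `feature_matrix` (must have no masked values; see
#'   [drop_masked_features()]).
#' @param classes Ordered severity factor, one per subject, with all three
#'   classes present (>= 2 subjects each).
#' @param alpha Significance level, default 0.0001.
#' @return data.frame: `feature_id`, `F`, `p`, `passed`.
#' @export
anova_screen <- function(fm, classes, alpha = GW_ALPHA_ANOVA) {
  X <- selection_values(fm, classes)
  res <- column_anova(X, classes)
  data.frame(feature_id = colnames(X), F = res$F, p = res$p,
             passed = !is.na(res$p) & res$p < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

selection_values <- function(fm, classes) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (anyNA(X))
    gw_validation_error("feature matrix contains masked values; drop them first")
  if (nrow(X) != length(classes))
    gw_validation_error("one class per subject is required")
  tab <- table(droplevels(factor(classes)))
  if (length(tab) < 3 && inherits(fm, "feature_matrix"))
    gw_validation_error("all three severity classes must be present")
  if (any(tab < 2))
    gw_validation_error("each severity class needs >= 2 subjects")
  X
}

#' Pairwise Student t-tests with Bonferroni-corrected threshold
#'
#' Two-sample pooled-variance (Student) t-tests between each pair of severity
#' classes, applied to the features that passed the ANOVA screen.
#'
#' @inheritParams anova_screen
#' @param screen Result of [anova_screen()]; pairwise tests are computed only
#'   for features with `passed = TRUE` (pass `NULL` to test everything).
#' @param alpha Corrected significance level, default 0.00003.
#' @param welch Use Welch's unequal-variance test instead of Student's.
#' @return data.frame: `feature_id`, `p_mild_moderate`, `p_moderate_severe`,
#'   `p_mild_severe`, `passed_all_pairs`. Undefined tests (zero pooled
#'   variance) yield `NA` p and do not pass.
#' @export
pairwise_ttests <- function(fm, classes, screen = NULL,
                            alpha = GW_ALPHA_PAIRWISE, welch = FALSE) {
  X <- selection_values(fm, classes)
  if (!is.null(screen)) {
    keep <- screen$feature_id[screen$passed]
    X <- X[, colnames(X) %in% keep, drop = FALSE]
  }
  lev <- severity_levels()
  pairs <- list(c("mild", "moderate"), c("moderate", "severe"),
                c("mild", "severe"))
  P <- sapply(pairs, function(pr)
    column_ttest(X, classes == pr[1], classes == pr[2], welch = welch)$p)
  if (!is.matrix(P)) P <- matrix(P, ncol = 3)
  passed <- rowSums(P < alpha) == 3L & !apply(P, 1, anyNA)
  data.frame(feature_id = colnames(X),
             p_mild_moderate = P[, 1], p_moderate_severe = P[, 2],
             p_mild_severe = P[, 3],
             passed_all_pairs = passed, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run the full two-gate selection procedure
#'
#' ANOVA screen followed by all-pairs Student t-tests; key features pass both
#' gates.
#'
#' @inheritParams anova_screen
#' @param alpha_anova,alpha_pairwise Gate significance levels.
#' @param bonferroni `"printed"` uses the published corrected level as given;
#'   `"exact"` uses `alpha_anova / 3`.
#' @param welch Passed to [pairwise_ttests()].
#' @return A `selection_result`: list with `table` (per-feature statistics and
#'   flags), `key_features` (ids ordered by ascending ANOVA p, ties broken by
#'   feature id) and the alphas used.
#' @export
select_features <- function(fm, classes,
                            alpha_anova = GW_ALPHA_ANOVA,
                            alpha_pairwise = GW_ALPHA_PAIRWISE,
                            bonferroni = c("printed", "exact"),
                            welch = FALSE) {
  bonferroni <- match.arg(bonferroni)
  if (bonferroni == "exact") alpha_pairwise <- alpha_anova / 3
  scr <- anova_screen(fm, classes, alpha = alpha_anova)
  tab <- scr
  tab$p_mild_moderate <- tab$p_moderate_severe <- tab$p_mild_severe <- NA_real_
  tab$passed_all_pairs <- FALSE
  if (any(scr$passed)) {
    tt <- pairwise_ttests(fm, classes, screen = scr, alpha = alpha_pairwise,
                          welch = welch)
    i <- match(tt$feature_id, tab$feature_id)
    tab$p_mild_moderate[i] <- tt$p_mild_moderate
    tab$p_moderate_severe[i] <- tt$p_moderate_severe
    tab$p_mild_severe[i] <- tt$p_mild_severe
    tab$passed_all_pairs[i] <- tt$passed_all_pairs
  }
  tab$key_feature <- tab$passed & tab$passed_all_pairs
  structure(list(table = tab,
                 key_features = order_key_features(tab),
                 alpha_anova = alpha_anova,
                 alpha_pairwise = alpha_pairwise),
            class = "selection_result")
}

order_key_features <- function(tab) {
  keys <- tab[tab$key_feature, , drop = FALSE]
  keys$feature_id[order(keys$p, keys$feature_id)]
}

#' Key features of a selection result
#' @param selection A `selection_result`.
#' @return Character vector of key feature ids, ordered by ascending ANOVA p.
#' @export
select_key_features <- function(selection) {
  if (!inherits(selection, "selection_result"))
    gw_validation_error("`selection` must be a selection_result")
  selection$key_features
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection: %d features screened, %d passed ANOVA (alpha %g), %d key (alpha %g)\n",
              nrow(x$table), sum(x$table$passed), x$alpha_anova,
              length(x$key_features), x$alpha_pairwise))
  invisible(x)
}

#' Subscale association of the key features
#'
#' Re-runs both gates (ANOVA, then all-pairs Student t-tests) with severity
#' classes defined by each WOMAC subscale score in turn, restricted to the key
#' features. A subscale whose classes leave some group with fewer than two
#' subjects is flagged unevaluable (`NULL` entry) and the others proceed.
#'
#' @param fm A `feature_matrix` restricted (or restrictable) to key features.
#' @param womac data.frame with `subject_id` and `item_01..item_24`, rows
#'   aligned with `fm`.
#' @param key_features Character vector of key feature ids.
#' @param alpha_anova,alpha_pairwise Gate significance levels.
#' @return Named list (`pain`, `stiffness`, `physical_function`) of feature-id
#'   vectors significant for that subscale (or `NULL` if unevaluable).
#' @export
subscale_association <- function(fm, womac, key_features,
                                 alpha_anova = GW_ALPHA_ANOVA,
                                 alpha_pairwise = GW_ALPHA_PAIRWISE) {
  sub <- womac_subscales()
  item_cols <- sprintf("item_%02d", 1:24)
  X <- fm$values[, colnames(fm$values) %in% key_features, drop = FALSE]
  fmk <- structure(list(subject_ids = fm$subject_ids,
                        registry = fm$registry[fm$registry$feature_id %in% key_features, ],
                        values = X, mask = is.na(X)),
                   class = "feature_matrix")
  out <- lapply(names(sub), function(sc) {
    score <- rowSums(womac[, item_cols[sub[[sc]]$items], drop = FALSE])
    cls <- classify_scale_scores(score, sc)
    if (length(unique(cls)) < 3 || any(table(cls) < 2)) {
      warning(sprintf("subscale '%s' unevaluable: a severity class has < 2 subjects", sc))
      return(NULL)
    }
    sel <- select_features(fmk, cls, alpha_anova = alpha_anova,
                           alpha_pairwise = alpha_pairwise)
    sel$key_features
  })
  names(out) <- names(sub)
  out
}
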