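# WOMAC instrument: scoring, cut points, severity classification.
#
# The WOMAC (Western Ontario and McMaster Universities Osteoarthritis Index)
# has 24 items scored 0 (no symptoms) to 4 (extreme): 5 pain, 2 stiffness and
# 17 physical-function items, giving a total in 0..96. Severity classes are
# derived from midpoint response levels: an average item response of 1.5 marks
# the mild/moderate transition and 2.5 the moderate/severe transition, so for
# a scale with `n` items the cut points are 1.5*n and 2.5*n (36 and 60 for the
# 24-item total).

#' WOMAC subscale structure
#'
#' Item counts and index blocks of the three WOMAC subscales, in the canonical
#' LK 3.0 item order (pain items 1-5, stiffness 6-7, physical function 8-24).
#'
#' @return Named list with `pain`, `stiffness` and `physical_function`, each a
#'   list holding `items` (integer index vector into the 24-item response
#'   vector) and `n_items`.
#' @export
#' @examples
#' womac_subscales()$pain$items
womac_subscales <- function() {
  list(
    pain              = list(items = 1:5,  n_items = 5L),
    stiffness         = list(items = 6:7,  n_items = 2L),
    physical_function = list(items = 8:24, n_items = 17L)
  )
}

#' Score a WOMAC response vector
#'
#' Computes total and subscale scores by plain summation (no weighting) from
#' the 24 item responses.
#'
#' @param items Integer vector of exactly 24 responses, each in 0..4, ordered
#'   pain (5), stiffness (2), physical function (17).
#' @param subject_id Optional identifier carried in the record.
#' @return A `womac_record`: list with `subject_id`, `items`, `total` (0..96)
#'   and `subscale_scores` (pain 0..20, stiffness 0..8, physical_function
#'   0..68).
#' @export
#' @examples
#' rec <- score_womac(rep(1L, 24))
#' rec$total
score_womac <- function(items, subject_id = NA_character_) {
  if (length(items) != 24L)
    gw_validation_error(sprintf(
      "WOMAC record must have exactly 24 items, got %d", length(items)))
  if (!is.numeric(items) || anyNA(items))
    gw_validation_error("WOMAC items must be numeric and non-missing")
  bad <- which(items < 0 | items > 4 | items != round(items))
  if (length(bad))
    gw_validation_error(sprintf(
      "WOMAC item(s) out of range 0..4 or non-integer at index: %s",
      paste(bad, collapse = ", ")))
  items <- as.integer(items)
  sub <- womac_subscales()
  scores <- vapply(sub, function(s) sum(items[s$items]), integer(1))
  structure(
    list(subject_id = subject_id,
         items = items,
         total = sum(items),
         subscale_scores = as.list(scores)),
    class = "womac_record")
}

#' Severity cut points for a WOMAC scale
#'
#' Cut points are the midpoint response levels 1.5 (mild/moderate) and 2.5
#' (moderate/severe) multiplied by the number of items in the scale; for the
#' 24-item total this gives 36 and 60.
#'
#' @param n_items Number of items in the scale (24 for the total; 5, 2 or 17
#'   for the subscales).
#' @return Numeric vector `c(lower = 1.5 * n_items, upper = 2.5 * n_items)`.
#' @export
#' @examples
#' severity_cutpoints(24)  # 36, 60
severity_cutpoints <- function(n_items) {
  stopifnot_scalar_number(n_items, "n_items")
  if (n_items < 1)
    gw_validation_error("`n_items` must be >= 1")
  c(lower = 1.5 * n_items, upper = 2.5 * n_items)
}

#' Severity labels, in order
#' @return Ordered factor levels used for severity classes.
#' @export
severity_levels <- function() c("mild", "moderate", "severe")

#' Classify scores into mild/moderate/severe
#'
#' Scores strictly below the lower cut point are mild, scores above the upper
#' cut point are severe, and both boundaries are inclusive to moderate
#' (36 and 60 map to moderate on the 24-item total). Set
#' `boundary = "strict"` for the half-open variant in which the boundaries
#' fall outward (lower boundary mild, upper boundary severe).
#'
#' @param score Numeric score(s) on the scale.
#' @param cutpoints Numeric `(lower, upper)` with `lower < upper`, as returned
#'   by [severity_cutpoints()].
#' @param max_score Optional maximum valid score; values outside
#'   `[0, max_score]` raise a validation error.
#' @param boundary `"inclusive"` (default) or `"strict"`.
#' @return Ordered factor with levels mild < moderate < severe, same length
#'   as `score`.
#' @export
#' @examples
#' classify_severity(c(35.9, 36, 60, 61), severity_cutpoints(24))
classify_severity <- function(score, cutpoints, max_score = NULL,
                              boundary = c("inclusive", "strict")) {
  boundary <- match.arg(boundary)
  if (length(cutpoints) != 2L || !all(is.finite(cutpoints)) ||
      cutpoints[1] >= cutpoints[2])
    gw_validation_error("`cutpoints` must be (lower, upper) with lower < upper")
  if (!is.numeric(score) || anyNA(score))
    gw_validation_error("`score` must be numeric and non-missing")
  if (any(score < 0))
    gw_validation_error("scores below 0 are outside the instrument range")
  if (!is.null(max_score) && any(score > max_score))
    gw_validation_error(sprintf(
      "score(s) above the instrument maximum %s", format(max_score)))
  lower <- cutpoints[[1]]; upper <- cutpoints[[2]]
  lab <- if (boundary == "inclusive") {
    ifelse(score < lower, "mild", ifelse(score <= upper, "moderate", "severe"))
  } else {
    # boundaries fall outward: the lower cut is mild, the upper cut severe
    ifelse(score <= lower, "mild", ifelse(score < upper, "moderate", "severe"))
  }
  factor(lab, levels = severity_levels(), ordered = TRUE)
}

#' Classify a WOMAC subscale score of a record
#'
#' Applies the same midpoint-based cut-point procedure as the total score,
#' using the subscale's own item count (cuts 7.5/12.5 for pain, 3/5 for
#' stiffness, 25.5/42.5 for physical function).
#'
#' @param record A `womac_record` from [score_womac()].
#' @param subscale One of `"pain"`, `"stiffness"`, `"physical_function"`.
#' @return Ordered severity factor of length 1.
#' @export
classify_subscale <- function(record, subscale) {
  sub <- womac_subscales()
  if (!is.character(subscale) || length(subscale) != 1L ||
      !subscale %in% names(sub))
    gw_validation_error(sprintf(
      "unknown subscale; must be one of: %s", paste(names(sub), collapse = ", ")))
  if (!inherits(record, "womac_record"))
    gw_validation_error("`record` must be a womac_record")
  n <- sub[[subscale]]$n_items
  classify_severity(record$subscale_scores[[subscale]],
                    severity_cutpoints(n), max_score = 4 * n)
}

#' Severity classes for a vector of scores on a named scale
#'
#' Convenience wrapper used by the pipeline: picks the item count for the
#' requested scale and classifies a whole cohort at once.
#'
#' @param scores Numeric vector of scores.
#' @param scale `"total"` or a subscale name.
#' @return Ordered severity factor.
#' @export
classify_scale_scores <- function(scores, scale = "total") {
  n <- if (identical(scale, "total")) 24L else {
    sub <- womac_subscales()
    if (!scale %in% names(sub))
      gw_validation_error(sprintf("unknown scale '%s'", scale))
    sub[[scale]]$n_items
  }
  classify_severity(scores, severity_cutpoints(n), max_score = 4 * n)
}

#' @export
print.womac_record <- function(x, ...) {
  cat(sprintf("WOMAC record %s: total %d (pain %d, stiffness %d, physical function %d)\n",
              x$subject_id, x$total,
              x$subscale_scores$pain, x$subscale_scores$stiffness,
              x$subscale_scores$physical_function))
  invisible(x)
}
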