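#' Postoperative outcome severity weights
#'
#' Severity weighting of postoperative events, from most to least severe:
#' death 7; prolonged ventilation (>24 h) 6; prolonged hospital stay
#' (>14 days) 5; discharge to a skilled nursing facility 4; stroke
#' (neurological deficit >72 h) 3; renal failure (creatinine >2 mg/dL) 3;
#' reoperation (>24 h post-op) 2; deep sternal wound infection 1.
#'
#' @return Named numeric vector of weights.
#' @export
outcome_weights <- function() {
  c(death = 7, prolonged_ventilation = 6, prolonged_stay = 5,
    snf_discharge = 4, stroke = 3, renal_failure = 3, reoperation = 2,
    dswi = 1)
}

#' Composite outcome severity score
#'
#' Maps a record of postoperative event flags to a severity score by the
#' published weights, combined by sum (default; a patient with several events
#' can exceed the single-event ceiling of 7) or by maximum.
#'
#' @param record Named logical vector, one-row data.frame, or character
#'   vector of event labels; names/labels must come from [outcome_weights()].
#' @param aggregation `"sum"` (default) or `"max"`.
#' @return Non-negative numeric score; 0 for no events.
#' @export
outcome_score <- function(record, aggregation = c("sum", "max")) {
  aggregation <- match.arg(aggregation)
  w <- outcome_weights()
  if (is.character(record)) {
    events <- record
  } else {
    record <- unlist(record[intersect(names(record), names(w))])
    if (!is.logical(record) && !all(record %in% c(0, 1))) {
      stop("event flags must be logical")
    }
    events <- names(record)[as.logical(record)]
  }
  bad <- setdiff(events, names(w))
  if (length(bad) > 0) stop("unknown outcome event(s): ",
                            paste(bad, collapse = ", "))
  if (length(events) == 0) return(0)
  if (aggregation == "sum") sum(w[events]) else max(w[events])
}

#' Classify frailty from 5-m gait speed
#'
#' A subject is frail when gait speed is strictly below the threshold
#' (default 0.833 m/s; a more severe conventional threshold of 0.65 m/s may
#' be supplied instead).
#'
#' @param speed Gait speed(s) in m/s; must be positive.
#' @param threshold Frailty threshold in m/s (default 0.833).
#' @return Character vector, `"frail"` or `"non-frail"`.
#' @export
classify_frailty <- function(speed, threshold = 0.833) {
  if (!is.numeric(speed) || any(!is.finite(speed)) || any(speed <= 0)) {
    stop("speed must be positive and finite")
  }
  ifelse(speed < threshold, "frail", "non-frail")
}

#' Per-variable group comparison
#'
#' Group means, SDs, coefficients of variation and a two-sample p-value for
#' each numeric feature, comparing two labelled groups (e.g. morbid vs
#' non-morbid, frail vs non-frail). Welch's t-test by default; a rank-based
#' Mann-Whitney option is available. Variables significant at p < 0.05 are
#' starred.
#'
#' @param features Data.frame of numeric feature columns.
#' @param labels Two-level factor/character/logical vector, one per row.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return Data.frame with one row per variable: per-group mean/sd/cv,
#'   `p_value` and `significant`.
#' @export
compare_groups <- function(features, labels, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  if (length(labels) != nrow(features)) stop("one label per feature row required")
  if (any(table(labels) < 2)) stop("each group needs at least 2 subjects")
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  if (length(num) == 0) stop("no numeric feature columns")
  g1 <- levels(labels)[1]; g2 <- levels(labels)[2]
  rows <- lapply(num, function(v) {
    x1 <- features[[v]][labels == g1]
    x2 <- features[[v]][labels == g2]
    p <- if (stats::sd(x1) == 0 && stats::sd(x2) == 0 &&
             mean(x1) == mean(x2)) {
      1  # identical degenerate groups: no evidence of difference
    } else if (test == "welch") {
      stats::t.test(x1, x2)$p.value
    } else {
      stats::wilcox.test(x1, x2, exact = FALSE)$p.value
    }
    data.frame(variable = v,
               mean_1 = mean(x1), sd_1 = stats::sd(x1),
               cv_1 = 100 * stats::sd(x1) / abs(mean(x1)),
               mean_2 = mean(x2), sd_2 = stats::sd(x2),
               cv_2 = 100 * stats::sd(x2) / abs(mean(x2)),
               p_value = p, significant = p < 0.05)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- c(g1, g2)
  out
}

#' Optimal cut-point for a single classifier variable
#'
#' Exhaustive scan over the midpoints between sorted unique values, returning
#' the threshold that maximizes sensitivity + specificity (Youden's index);
#' ties are broken toward higher sensitivity, then toward the first (lowest)
#' candidate.
#'
#' @param values Numeric classifier variable.
#' @param labels Binary labels (logical or 0/1); `TRUE`/1 is the positive
#'   (e.g. morbid) class.
#' @param direction `"<="` if low values predict the positive class (default)
#'   or `">"` if high values do.
#' @param variable Optional variable name carried into the rule.
#' @return An object of class `cutoff_rule`: `variable`, `direction`,
#'   `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
cutpoint_analysis <- function(values, labels, direction = c("<=", ">"),
                              variable = NA_character_) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(values) != length(labels)) stop("values and labels must align")
  if (any(!is.finite(values)) || any(is.na(labels))) {
    stop("values and labels must be complete")
  }
  if (!any(labels) || all(labels)) {
    stop("both classes must be present for cut-point analysis")
  }
  u <- sort(unique(values))
  if (length(u) < 2) stop("need at least two distinct values")
  candidates <- (u[-1] + u[-length(u)]) / 2
  npos <- sum(labels); nneg <- sum(!labels)
  best <- NULL
  for (thr in candidates) {
    pred <- if (direction == "<=") values <= thr else values > thr
    sens <- sum(pred & labels) / npos
    spec <- sum(!pred & !labels) / nneg
    j <- sens + spec
    if (is.null(best) || j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 && sens > best$sensitivity + 1e-12)) {
      best <- list(threshold = thr, sensitivity = sens, specificity = spec,
                   youden = j)
    }
  }
  structure(c(list(variable = variable, direction = direction), best),
            class = "cutoff_rule")
}

#' @export
print.cutoff_rule <- function(x, ...) {
  cat(sprintf("<cutoff_rule> %s %s %.4g: sensitivity %.3f, specificity %.3f\n",
              if (is.na(x$variable)) "value" else x$variable, x$direction,
              x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Published morbidity cut-off rules
#'
#' The reported single-variable cut-offs with highest morbidity
#' classification sensitivity: smartphone walking velocity <= 0.716 m/s,
#' RMS_V <= 0.137 g, inter-step time > 0.533 s, ApEn of the resultant sway
#' direction <= 1.139.
#'
#' @return Data.frame with columns `variable`, `direction`, `threshold`.
#' @export
published_cutoff_rules <- function() {
  data.frame(
    variable = c("smartphone_velocity", "rms_v", "step_time", "apen_r_cop"),
    direction = c("<=", "<=", ">", "<="),
    threshold = c(0.716, 0.137, 0.533, 1.139)
  )
}
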