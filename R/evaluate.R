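# Parameter evaluation: ROC construction, refixation-threshold optimisation,
# test-retest statistics, and the two-criterion retention rule.

#' Empirical ROC of a screening parameter
#'
#' Builds the empirical ROC for discriminating dyslexic from control readers
#' on a single parameter. The positive class is dyslexic; the decision rule
#' is `value >= threshold` when the parameter runs high in dyslexic readers,
#' and `value <= threshold` otherwise — the orientation is chosen so the
#' area is at least 0.5 and is stored. Thresholds run over all observed
#' values; the area is computed by the trapezoid rule, which handles ties by
#' midranks (it equals the tie-corrected Mann-Whitney statistic
#' U/(n1*n2)).
#'
#' @param values_control,values_dyslexic Parameter values per group.
#' @return Object of class `roc_result`: thresholds, sens, spec, area
#'   (oriented), area_raw (dyslexic-high convention), direction
#'   (">=" or "<="), best_threshold, sens_best, spec_best.
#' @export
roc_area <- function(values_control, values_dyslexic) {
  if (!length(values_control) || !length(values_dyslexic))
    stop("both groups must be non-empty")
  raw <- .roc_curve(values_control, values_dyslexic, direction = ">=")
  if (raw$area >= 0.5) {
    roc <- raw
    roc$direction <- ">="
  } else {
    roc <- .roc_curve(values_control, values_dyslexic, direction = "<=")
    roc$direction <- "<="
  }
  roc$area_raw <- raw$area
  bt <- .closest_to_perfect(roc)
  roc$best_threshold <- bt$threshold
  roc$sens_best <- bt$sens
  roc$spec_best <- bt$spec
  class(roc) <- "roc_result"
  roc
}

# ROC points over all observed thresholds; direction ">=" flags high values
# as positive (dyslexic), "<=" flags low values.
.roc_curve <- function(ctrl, dysl, direction) {
  thr <- sort(unique(c(ctrl, dysl)))
  if (direction == ">=") {
    sens <- vapply(thr, function(c) mean(dysl >= c), numeric(1))
    spec <- vapply(thr, function(c) mean(ctrl < c), numeric(1))
  } else {
    sens <- vapply(thr, function(c) mean(dysl <= c), numeric(1))
    spec <- vapply(thr, function(c) mean(ctrl > c), numeric(1))
  }
  # close the curve at (0,0) and (1,1) in ROC space
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  o <- order(fpr, tpr)
  area <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
  list(thresholds = thr, sens = sens, spec = spec, area = area)
}

.closest_to_perfect <- function(roc) {
  d2 <- (1 - roc$spec)^2 + (1 - roc$sens)^2
  best <- which(d2 == min(d2))
  if (length(best) > 1) best <- best[which.max(roc$spec[best])]
  list(threshold = roc$thresholds[best], sens = roc$sens[best],
       spec = roc$spec[best])
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: area %.3f (direction dyslexic %s threshold); best threshold %.3g (sens %.2f, spec %.2f)\n",
              x$area, x$direction, x$best_threshold, x$sens_best, x$spec_best))
  invisible(x)
}

#' Threshold on a ROC curve closest to the ideal point
#'
#' Returns the threshold whose (1-specificity, sensitivity) point minimises
#' the Euclidean distance to the perfect classifier at (0, 1); ties are
#' broken towards higher specificity.
#'
#' @param roc A [roc_area()] result.
#' @return The threshold value.
#' @export
best_threshold <- function(roc) .closest_to_perfect(roc)$threshold

#' Optimise the backward-refixation length threshold
#'
#' For each candidate threshold (pixels), recomputes the per-participant
#' refixation count R and the ROC area it achieves for separating the two
#' groups; returns the raw argmax over the grid (ties resolve to the
#' smallest threshold) together with the area-vs-threshold curve.
#'
#' @param saccade_list List of saccade data.frames, one per participant.
#' @param groups Character vector ("control"/"dyslexic") parallel to
#'   `saccade_list`.
#' @param grid Candidate thresholds in pixels.
#' @return List: threshold (argmax), grid, areas.
#' @export
optimize_refixation_threshold <- function(saccade_list, groups,
                                          grid = seq(100, 400, by = 10)) {
  stopifnot(length(saccade_list) == length(groups))
  areas <- vapply(grid, function(thr) {
    R <- vapply(saccade_list, count_refixations, numeric(1),
                threshold_px = thr)
    roc_area(R[groups == "control"], R[groups == "dyslexic"])$area
  }, numeric(1))
  list(threshold = grid[which.max(areas)], grid = grid, areas = areas)
}

#' Test-retest stability statistics
#'
#' Mean absolute test-retest difference (with SD) within each group, and the
#' Pearson correlation of test vs retest values over the combined
#' population.
#'
#' @param test,retest Paired parameter values (same participants, same
#'   order).
#' @param groups "control"/"dyslexic" per participant.
#' @return List: mean_abs_diff_control, sd_control, mean_abs_diff_dyslexic,
#'   sd_dyslexic, pearson_r, n.
#' @export
retest_stats <- function(test, retest, groups) {
  if (length(test) != length(retest) || length(test) != length(groups))
    stop("test, retest and groups must be paired (equal length)")
  d <- abs(test - retest)
  ctl <- groups == "control"; dys <- groups == "dyslexic"
  list(mean_abs_diff_control = mean(d[ctl]),
       sd_control = stats::sd(d[ctl]),
       mean_abs_diff_dyslexic = mean(d[dys]),
       sd_dyslexic = stats::sd(d[dys]),
       pearson_r = stats::cor(test, retest),
       n = length(test))
}

#' Two-criterion parameter retention rule
#'
#' A parameter is retained for the total score when (i) its ROC area is at
#' least `area_min` and (ii) the absolute control-dyslexic mean difference
#' is at least `factor` times the larger of the two within-group mean
#' absolute test-retest differences.
#'
#' @param area ROC area of the parameter.
#' @param mean_diff Control mean minus dyslexic mean.
#' @param retest_control,retest_dyslexic Within-group mean absolute
#'   test-retest differences.
#' @param area_min Retention threshold on the ROC area.
#' @param factor Required ratio of mean difference to retest variability.
#' @return Logical: retained or not.
#' @export
retention_check <- function(area, mean_diff, retest_control, retest_dyslexic,
                            area_min = 0.87, factor = 2) {
  area >= area_min &&
    abs(mean_diff) >= factor * max(retest_control, retest_dyslexic)
}
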