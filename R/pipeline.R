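# End-to-end screening pipeline: detection -> parameters -> norms ->
# evaluation -> classifier -> screening report.

#' Pipeline configuration
#'
#' Collects every tunable of the screening pipeline with its default:
#' detection thresholds (90 ms, 45 px, 100 deg/s), the refixation length
#' threshold (100 px) and its optimisation grid (100-400 px), the
#' word-length bins, the retention rule (ROC area >= 0.87, mean difference
#' >= 2x retest variability), the classifier settings and the assumed
#' prevalence (10%).
#'
#' @param detection A [detection_config()].
#' @param refix_threshold Backward-refixation length threshold (px).
#' @param refix_grid Candidate grid for [optimize_refixation_threshold()].
#' @param bins Word-length bins ([radar_text_bins()]).
#' @param area_min,retest_factor Retention rule constants.
#' @param shrinkage,priors Classifier settings ([trs()]).
#' @param prevalence Assumed population prevalence for the screening report.
#' @param score_cutoff Gaze-difficulty score cutoff.
#' @return List of class `radar_config`.
#' @export
radar_config <- function(detection = detection_config(),
                         refix_threshold = 100,
                         refix_grid = seq(100, 400, by = 10),
                         bins = radar_text_bins("basic"),
                         area_min = 0.87, retest_factor = 2,
                         shrinkage = 0.2,
                         priors = c(control = 0.5, dyslexic = 0.5),
                         prevalence = 0.1, score_cutoff = 0.9) {
  structure(list(detection = detection, refix_threshold = refix_threshold,
                 refix_grid = refix_grid, bins = bins, area_min = area_min,
                 retest_factor = retest_factor, shrinkage = shrinkage,
                 priors = priors, prevalence = prevalence,
                 score_cutoff = score_cutoff),
            class = "radar_config")
}

#' Detect events of one recording
#'
#' Runs fixation detection, saccade extraction and word assignment for one
#' recording against a layout.
#'
#' @param rec A `gaze_recording`.
#' @param layout The `text_layout` that was read.
#' @param cfg A [radar_config()].
#' @return List: fixations, saccades, word_idx, first_pass (visits + counts).
#' @export
recording_events <- function(rec, layout, cfg = radar_config()) {
  fix <- detect_fixations(rec, cfg$detection)
  sacc <- extract_saccades(fix, cfg$detection, layout$geometry,
                           line_width_px = layout$line_width_px,
                           line_spacing_px = layout$line_spacing_px)
  widx <- assign_fixations_to_words(fix, layout)
  fp <- first_pass_analysis(widx, fix$duration, nrow(layout$boxes))
  list(fixations = fix, saccades = sacc, word_idx = widx,
       first_pass = fp)
}

#' Compute the parameter table of a cohort
#'
#' Computes, per recording, the general parameters (tau and the fitted mu
#' and sigma, saccade quartiles, refixations R, fixation count Fix) and the
#' word-specific parameters (F0, F1, Fge2 and the gaze-difficulty X bins).
#' Word norms are built per session from that session's control readers;
#' each control participant is scored against norms that exclude them
#' (leave-one-out norms), dyslexic readers against the full control norms.
#'
#' @param cohort A `reading_cohort` (or list with recordings, labels,
#'   layout).
#' @param cfg A [radar_config()].
#' @return data.frame: participant_id, group, session, then one column per
#'   parameter.
#' @export
cohort_parameters <- function(cohort, cfg = radar_config()) {
  labels <- cohort$labels
  layout <- cohort$layout
  events <- lapply(seq_len(nrow(labels)), function(i) {
    key <- paste0(labels$participant_id[i], ".", labels$session[i])
    recording_events(cohort$recordings[[key]], layout, cfg)
  })
  rows <- vector("list", nrow(labels))
  for (ses in unique(labels$session)) {
    in_ses <- which(labels$session == ses)
    ctl <- in_ses[labels$group[in_ses] == "control"]
    G <- .gaze_matrix(lapply(events[ctl], function(e) e$first_pass$visits))
    full_norms <- .norms_from_matrix(G)
    for (i in in_ses) {
      e <- events[[i]]
      norms <- if (labels$group[i] == "control")
        .norms_from_matrix(G, exclude_row = match(i, ctl))
      else full_norms
      X <- gaze_difficulty_counts(e$first_pass$visits, norms, layout,
                                  cfg$bins, cutoff = cfg$score_cutoff)
      egf <- fit_exgaussian(e$fixations$duration)
      q <- saccade_quartiles(e$saccades)
      rows[[i]] <- data.frame(
        participant_id = labels$participant_id[i], group = labels$group[i],
        session = labels$session[i],
        tau = egf$tau, mu = egf$mu, sigma = egf$sigma,
        q25 = q[["q25"]], q50 = q[["q50"]], q75 = q[["q75"]],
        R = count_refixations(e$saccades, cfg$refix_threshold),
        Fix = count_fixations(e$fixations),
        F0 = e$first_pass$counts[["F0"]],
        F1 = e$first_pass$counts[["F1"]],
        Fge2 = e$first_pass$counts[["Fge2"]],
        stringsAsFactors = FALSE)
      for (nm in names(X)) rows[[i]][[nm]] <- X[[nm]]
    }
  }
  do.call(rbind, rows)
}

#' Evaluate parameters for retention
#'
#' Builds the evaluation table: per parameter, the ROC area between groups
#' (test session), the within-group mean absolute test-retest differences
#' (with SD), the control-dyslexic mean difference, the combined-population
#' test-retest Pearson r, and the retention decision under the
#' two-criterion rule.
#'
#' @param params Output of [cohort_parameters()] (test + retest sessions).
#' @param cfg A [radar_config()].
#' @param parameters Which parameter columns to evaluate.
#' @return data.frame, one row per parameter.
#' @export
evaluate_parameters <- function(params, cfg = radar_config(),
                                parameters = setdiff(
                                  colnames(params),
                                  c("participant_id", "group", "session"))) {
  test <- params[params$session == "test", ]
  retest <- params[params$session == "retest", ]
  has_retest <- nrow(retest) > 0
  if (has_retest) {
    common <- intersect(test$participant_id, retest$participant_id)
    t2 <- test[match(common, test$participant_id), ]
    r2 <- retest[match(common, retest$participant_id), ]
  }
  out <- lapply(parameters, function(p) {
    roc <- roc_area(test[[p]][test$group == "control"],
                    test[[p]][test$group == "dyslexic"])
    mean_diff <- mean(test[[p]][test$group == "control"]) -
      mean(test[[p]][test$group == "dyslexic"])
    row <- data.frame(parameter = p, A_ROC = roc$area,
                      mean_diff = mean_diff,
                      best_threshold = roc$best_threshold,
                      sens_best = roc$sens_best, spec_best = roc$spec_best,
                      direction = roc$direction,
                      stringsAsFactors = FALSE)
    if (has_retest) {
      rs <- retest_stats(t2[[p]], r2[[p]], t2$group)
      row$retest_control <- rs$mean_abs_diff_control
      row$retest_control_sd <- rs$sd_control
      row$retest_dyslexic <- rs$mean_abs_diff_dyslexic
      row$retest_dyslexic_sd <- rs$sd_dyslexic
      row$pearson_r <- rs$pearson_r
      row$retained <- retention_check(roc$area, mean_diff,
                                      rs$mean_abs_diff_control,
                                      rs$mean_abs_diff_dyslexic,
                                      cfg$area_min, cfg$retest_factor)
    }
    row
  })
  do.call(rbind, out)
}

#' Run the full screening pipeline on a cohort
#'
#' Executes detection, parameter computation, parameter evaluation,
#' classifier fitting with leave-one-out validation, and the prevalence-
#' conditional screening report, in one call.
#'
#' @param cohort A `reading_cohort` (e.g. from [generate_cohort()]).
#' @param cfg A [radar_config()].
#' @return Object of class `radar_report`: list with `params`, `evaluation`,
#'   `model` (a [trs()] fit on the test session), `cv` (a `trs_cv`),
#'   `screening` (a `screening_report`), `config`.
#' @examples
#' \donttest{
#' co <- generate_cohort(10, 10, with_retest = FALSE, seed = 1)
#' rep <- radar_pipeline(co)
#' rep$cv
#' }
#' @export
radar_pipeline <- function(cohort, cfg = radar_config()) {
  params <- cohort_parameters(cohort, cfg)
  evaluation <- evaluate_parameters(params, cfg)
  test <- params[params$session == "test", ]
  cols <- trs_parameters(cfg$bins)
  x <- as.matrix(test[, cols])
  rownames(x) <- test$participant_id
  model <- trs(x, test$group, shrinkage = cfg$shrinkage, priors = cfg$priors)
  cv <- trs_loocv(x, test$group, shrinkage = cfg$shrinkage,
                  priors = cfg$priors)
  screening <- post_test(cfg$prevalence, 100 * cv$sensitivity,
                         100 * cv$specificity)
  structure(list(params = params, evaluation = evaluation, model = model,
                 cv = cv, screening = screening, config = cfg),
            class = "radar_report")
}

#' @export
print.radar_report <- function(x, ...) {
  cat("== Reading-screening pipeline report ==\n")
  print(x$model)
  print(x$cv)
  ret <- x$evaluation$parameter[isTRUE(x$evaluation$retained) |
                                  x$evaluation$retained %in% TRUE]
  if (length(ret))
    cat("Retained parameters:", paste(ret, collapse = ", "), "\n")
  print(x$screening)
  invisible(x)
}
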