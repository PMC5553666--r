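mk_fix <- function(cx, cy, screen = 1, dur = 200) {
  n <- length(cx)
  data.frame(cx = cx, cy = cy, t_start = seq(0, by = 250, length.out = n),
             duration = rep_len(dur, n), n_samples = 12,
             screen = rep_len(screen, n), segment = 1)
}

test_that("fixations map to the word box under them and respect tolerances", {
  lay <- build_layout("alpha beta gamma delta epsilon", max_line_chars = 12)
  b <- lay$boxes
  ctr <- mk_fix((b$x0 + b$x1) / 2, (b$y0 + b$y1) / 2, screen = b$screen)
  expect_equal(assign_fixations_to_words(ctr, lay), seq_len(nrow(b)))
  # vertically beyond the tolerance of every line: unassigned
  off <- mk_fix(b$x0[1] + 5, b$y0[1] - lay$line_spacing_px / 2 - 20)
  expect_true(is.na(assign_fixations_to_words(off, lay)))
  # horizontally outside all margins: unassigned
  out <- mk_fix(b$x1[nrow(b)] + 200, (b$y0[nrow(b)] + b$y1[nrow(b)]) / 2,
                screen = b$screen[nrow(b)])
  expect_true(is.na(assign_fixations_to_words(out, lay)))
})

test_that("zero-jitter scanpaths are assigned exactly as planned", {
  # words of >= 5 characters keep planned fixations farther apart than the
  # dispersion window, so detection reproduces the plan exactly
  lay <- build_layout(paste(rep(c("alpha", "bravo", "candle", "deltas",
                                  "echoes", "foxtrot", "golfer", "hotels"),
                                4), collapse = " "))
  rec <- simulate_reading(lay, clean_profile(p_refix = 0.2, p_regress = 0.2),
                          seed = 31)
  truth <- attr(rec, "truth")
  f <- detect_fixations(rec)
  expect_equal(nrow(f), nrow(truth))
  widx <- assign_fixations_to_words(f, lay)
  expect_equal(widx, truth$word)
})

test_that("first-pass analysis follows the run definition and conserves word classes", {
  # scanpath w1, w1, w2, w1: w1 first pass has two fixations, one revisit
  res <- first_pass_analysis(c(1, 1, 2, 1), c(200, 150, 220, 180), n_words = 3)
  v <- res$visits
  expect_equal(v$first_pass_fix_count, c(2, 1, 0))
  expect_equal(v$first_pass_gaze, c(350, 220, 0))
  expect_equal(v$revisits, c(1, 0, 0))
  expect_equal(unname(res$counts), c(1, 1, 1))  # F0 (w3), F1 (w2), Fge2 (w1)

  # one fixation per word in order
  res2 <- first_pass_analysis(1:10, rep(150, 10), n_words = 10)
  expect_equal(unname(res2$counts), c(0, 10, 0))
  expect_true(all(res2$visits$revisits == 0))

  # unassigned fixations are dropped before runs form
  res3 <- first_pass_analysis(c(1, NA, 1, 2), rep(100, 4), n_words = 2)
  expect_equal(res3$visits$first_pass_fix_count, c(2, 1))
})

test_that("F0 + F1 + Fge2 equals the word count on simulated scanpaths", {
  lay <- radar_text("basic")$layout
  for (s in 1:5) {
    prof <- if (s %% 2) control_profile() else dyslexic_profile()
    rec <- simulate_reading(lay, prof, seed = 400 + s)
    f <- detect_fixations(rec)
    widx <- assign_fixations_to_words(f, lay)
    res <- first_pass_analysis(widx, f$duration, nrow(lay$boxes))
    expect_equal(sum(res$counts), nrow(lay$boxes))
  }
})

test_that("control norms are the per-word mean/SD over fixating controls", {
  mk_visits <- function(gaze) {
    data.frame(word_idx = seq_along(gaze), first_pass_gaze = ifelse(is.na(gaze), 0, gaze),
               first_pass_fix_count = ifelse(is.na(gaze), 0L, 1L),
               revisits = 0L)
  }
  vis <- list(mk_visits(c(200, NA, 300)),
              mk_visits(c(220, NA, 310)),
              mk_visits(c(240, NA, NA)))
  norms <- build_control_norms(vis)
  expect_equal(norms$mean_gaze[1], 220)
  expect_equal(norms$sd_gaze[1], 20)
  expect_equal(norms$n_contributing[2], 0)
  expect_true(is.na(norms$mean_gaze[2]))  # skipped by all controls
  expect_equal(norms$mean_gaze[3], 305)
  expect_equal(norms$n_contributing[3], 2)
})

test_that("norms equal a brute-force per-word recomputation on a simulated cohort", {
  co <- small_cohort()
  lab <- co$labels
  ctl_ids <- lab$participant_id[lab$group == "control"]
  vis <- lapply(ctl_ids, function(id) {
    rec <- co$recordings[[paste0(id, ".test")]]
    f <- detect_fixations(rec)
    widx <- assign_fixations_to_words(f, co$layout)
    first_pass_analysis(widx, f$duration, nrow(co$layout$boxes))$visits
  })
  norms <- build_control_norms(vis)
  for (w in sample(seq_len(nrow(co$layout$boxes)), 25)) {
    g <- vapply(vis, function(v)
      if (v$first_pass_fix_count[w] > 0) v$first_pass_gaze[w] else NA_real_,
      numeric(1))
    g <- g[!is.na(g)]
    if (length(g) >= 2) {
      expect_equal(norms$mean_gaze[w], mean(g))
      expect_equal(norms$sd_gaze[w], sd(g))
    } else {
      expect_true(is.na(norms$mean_gaze[w]))
    }
  }
})

test_that("gaze-difficulty counts flag scores strictly above the cutoff into length bins", {
  lay <- build_layout("aa bbbb cccccc ddddddddd")  # lengths 2, 4, 6, 9
  bins <- radar_text_bins("basic")
  norms <- data.frame(word_idx = 1:4, mean_gaze = rep(200, 4),
                      sd_gaze = rep(40, 4), n_contributing = 5)
  at_mean <- data.frame(word_idx = 1:4, first_pass_gaze = rep(200, 4),
                        first_pass_fix_count = 1L, revisits = 0L)
  expect_equal(sum(gaze_difficulty_counts(at_mean, norms, lay, bins)), 0)

  # gaze at mean + 1.5 sd on the 9-letter word: score pnorm(1.5) ~ 0.933
  hi <- at_mean; hi$first_pass_gaze[4] <- 200 + 1.5 * 40
  X <- gaze_difficulty_counts(hi, norms, lay, bins)
  expect_equal(X[["X_ge8"]], 1)
  expect_equal(sum(X), 1)
  # raising the cutoff above the score empties the bin
  expect_equal(sum(gaze_difficulty_counts(hi, norms, lay, bins,
                                          cutoff = 0.95)), 0)
  # skipped words and unavailable norms contribute nothing
  sk <- hi; sk$first_pass_fix_count[4] <- 0L
  expect_equal(sum(gaze_difficulty_counts(sk, norms, lay, bins)), 0)
  norms2 <- norms; norms2$mean_gaze[4] <- NA
  expect_equal(sum(gaze_difficulty_counts(hi, norms2, lay, bins)), 0)
})

test_that("raising the score cutoff never increases any difficulty count", {
  p <- small_params()  # X columns computed at cutoff 0.9
  co <- small_cohort()
  cfg95 <- radar_config(score_cutoff = 0.95)
  p95 <- cohort_parameters(co, cfg95)
  for (col in c("X_le3", "X_45", "X_67", "X_ge8")) {
    expect_true(all(p95[[col]] <= p[[col]]))
  }
})

test_that("scoring controls against own-cohort norms flags about 10% of words", {
  p <- small_params()
  ctl <- p[p$group == "control", ]
  lay <- small_cohort()$layout
  # expected scored words per participant is bounded by non-skipped words
  frac <- sum(ctl[, c("X_le3", "X_45", "X_67", "X_ge8")]) /
    sum(nrow(lay$boxes) - ctl$F0)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.25)
})
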