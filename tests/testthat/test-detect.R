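frame <- 1000 / 60

test_that("a stationary cloud becomes one fixation; sub-t_min clouds none", {
  t <- (0:29) * frame
  rec <- as_recording(rep(500, 30), rep(300, 30), t)
  f <- detect_fixations(rec)
  expect_equal(nrow(f), 1)
  expect_equal(f$cx, 500)
  expect_equal(f$cy, 300)
  expect_equal(f$duration, 29 * frame, tolerance = 1e-9)

  # 4 samples (~50 ms) then a 200 px jump: the first cloud is too short
  x <- c(rep(100, 4), rep(300, 30))
  rec2 <- as_recording(x, rep(300, 34), (0:33) * frame)
  f2 <- detect_fixations(rec2)
  expect_equal(nrow(f2), 1)
  expect_equal(f2$cx, 300)
})

test_that("detector matches the brute-force dispersion oracle on random streams", {
  cfg <- detection_config()
  set.seed(2024)
  for (k in 1:100) {
    n <- sample(50:1000, 1)
    # piecewise-stationary path with jumps and jitter
    n_seg <- max(2, rpois(1, n / 40))
    seg_len <- as.vector(table(sample(n_seg, n, replace = TRUE)))
    cx <- runif(length(seg_len), 100, 1200)
    cy <- runif(length(seg_len), 100, 700)
    x <- unlist(mapply(function(c, l) c + rnorm(l, 0, runif(1, 0, 25)),
                       cx, seg_len, SIMPLIFY = FALSE))
    y <- unlist(mapply(function(c, l) c + rnorm(l, 0, runif(1, 0, 25)),
                       cy, seg_len, SIMPLIFY = FALSE))
    t <- (seq_along(x) - 1) * frame
    got <- detect_fixations(as_recording(x, y, t), cfg)
    want <- idt_oracle(x, y, t, cfg$t_min, cfg$d_max)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$cx, want$cx)
    expect_equal(got$cy, want$cy)
    expect_equal(got$t_start, want$t_start)
    expect_equal(got$duration, want$duration)
    expect_equal(got$n_samples, want$n_samples)
  }
})

test_that("emitted fixations satisfy the duration and dispersion thresholds and are disjoint", {
  cfg <- detection_config()
  rec <- small_cohort()$recordings[[1]]
  f <- detect_fixations(rec, cfg)
  expect_true(all(f$duration >= cfg$t_min))
  expect_true(all(f$n_samples >= 2))
  # re-check dispersion of each emitted cloud post hoc
  s <- rec$samples
  for (i in seq_len(nrow(f))) {
    idx <- which(s$valid & s$t_ms >= f$t_start[i] &
                   s$t_ms <= f$t_start[i] + f$duration[i] &
                   s$screen == f$screen[i])
    expect_lte(max(diff(range(s$x_px[idx])), diff(range(s$y_px[idx]))),
               cfg$d_max)
  }
  expect_true(all(diff(f$t_start) > 0))
  expect_true(all(f$t_start[-1] >= (f$t_start + f$duration)[-nrow(f)]))
})

test_that("lowering d_max never decreases the number of fixation boundaries", {
  rec <- small_cohort()$recordings[[2]]
  counts <- vapply(c(60, 45, 30, 20), function(d)
    nrow(detect_fixations(rec, detection_config(d_max = d))), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("blink intervals are reported and match the simulator's insertion log", {
  rec_ok <- as_recording(rep(10, 30), rep(10, 30), (0:29) * frame)
  expect_equal(nrow(detect_blinks(rec_ok)), 0)

  v <- rep(TRUE, 60); v[20:28] <- FALSE  # 9 invalid frames ~ 133 ms
  rec_b <- as_recording(rep(10, 60), rep(10, 60), (0:59) * frame, valid = v)
  b <- detect_blinks(rec_b)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_samples, 9)
  expect_equal(b$duration_ms, 8 * frame, tolerance = 1e-9)

  rec <- simulate_reading(radar_text("basic")$layout,
                          control_profile(blink_rate_per_min = 12), seed = 5)
  log <- attr(rec, "blinks")
  got <- detect_blinks(rec)
  expect_equal(nrow(got), nrow(log))
  expect_equal(got$t_start_ms, log$t_start_ms)
  expect_equal(got$n_samples, log$n_samples)
})

test_that("a blink terminates the ongoing fixation window", {
  # one stationary cloud split by a 5-frame blink: two fixations, not one
  v <- rep(TRUE, 60); v[25:29] <- FALSE
  rec <- as_recording(rep(400, 60), rep(400, 60), (0:59) * frame, valid = v)
  f <- detect_fixations(rec)
  expect_equal(nrow(f), 2)
  # and the blink-spanning transition yields no saccade
  s <- extract_saccades(f)
  expect_equal(nrow(s), 0)
})

test_that("saccade recognition applies the speed criterion", {
  g <- screen_geometry()
  cfg <- detection_config()
  # two fixations 1.65 degrees apart with a 16 ms gap: ~103 deg/s, a saccade
  mk_fix <- function(cx, t0, dur) data.frame(cx = cx, cy = 300, t_start = t0,
                                             duration = dur, n_samples = 10,
                                             screen = 1, segment = 1)
  f <- rbind(mk_fix(500, 0, 150), mk_fix(500 + deg_to_px(1.65, g), 166, 150))
  s <- extract_saccades(f, cfg, g)
  expect_equal(nrow(s), 1)
  expect_equal(s$speed, 1.65 / 0.016, tolerance = 0.005)
  expect_gt(s$speed, 100)
  expect_false(s$is_backward)

  # identical centres: zero length, zero speed, no saccade
  f2 <- rbind(mk_fix(500, 0, 150), mk_fix(500, 166, 150))
  expect_equal(nrow(extract_saccades(f2, cfg, g)), 0)

  # a slow drift transition is dropped without merging fixations
  f3 <- rbind(mk_fix(500, 0, 150), mk_fix(530, 400, 150))
  expect_equal(nrow(extract_saccades(f3, cfg, g)), 0)
  expect_error(saccade_quartiles(extract_saccades(f3, cfg, g)))
  expect_equal(nrow(extract_saccades(f3[1, ], cfg, g)), 0)
})

test_that("saccade count equals fixation transitions minus blink-spanning and sub-speed ones", {
  cfg <- detection_config()
  rec <- small_cohort()$recordings[[3]]
  f <- detect_fixations(rec, cfg)
  s <- extract_saccades(f, cfg, rec$geometry,
                        line_width_px = rec$layout_info$line_width_px,
                        line_spacing_px = rec$layout_info$line_spacing_px)
  i <- seq_len(nrow(f) - 1)
  gap <- f$t_start[i + 1] - (f$t_start[i] + f$duration[i])
  dist <- sqrt((f$cx[i + 1] - f$cx[i])^2 + (f$cy[i + 1] - f$cy[i])^2)
  speed <- px_to_deg(dist, rec$geometry) / (gap / 1000)
  expected <- sum(f$segment[i] == f$segment[i + 1] & speed > cfg$speed_min)
  expect_equal(nrow(s), expected)
  expect_equal(s$is_backward, s$length_x < 0)
})

test_that("line-return sweeps are flagged by the leftward-and-down rule", {
  lay <- radar_text("basic")$layout
  rec <- simulate_reading(lay, clean_profile(), seed = 3)
  f <- detect_fixations(rec)
  s <- extract_saccades(f, g = rec$geometry,
                        line_width_px = rec$layout_info$line_width_px,
                        line_spacing_px = rec$layout_info$line_spacing_px)
  # a no-skip reading visits every line; every within-screen line change
  # is a return sweep
  st <- layout_stats(lay)
  expect_equal(sum(s$is_line_return), st$n_lines - st$n_screens)
  expect_true(all(s$length_x[s$is_line_return] < -300))
})
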