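# Independent oracles and shared fixtures for the test suite.

# Brute-force dispersion-threshold fixation finder: same contract as the
# package detector but recomputes window dispersion from scratch at every
# expansion (O(n^2)); used as the reference on short streams.
idt_oracle <- function(x, y, t, t_min, d_max) {
  disp <- function(a, b) max(diff(range(x[a:b])), diff(range(y[a:b])))
  n <- length(x)
  rows <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && t[j] - t[i] < t_min) j <- j + 1L
    if (t[j] - t[i] < t_min) break
    if (disp(i, j) > d_max) { i <- i + 1L; next }
    while (j < n && disp(i, j + 1L) <= d_max) j <- j + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      cx = mean(x[i:j]), cy = mean(y[i:j]), t_start = t[i],
      duration = t[j] - t[i], n_samples = j - i + 1L)
    i <- j + 1L
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(cx = numeric(0), cy = numeric(0), t_start = numeric(0),
                  duration = numeric(0), n_samples = integer(0))
}

# Tie-corrected rank-statistic AUC: U/(n1*n2) with midranks,
# dyslexic-high orientation.
auc_rank_oracle <- function(ctrl, dysl) {
  r <- rank(c(dysl, ctrl))
  nd <- length(dysl); nc <- length(ctrl)
  (sum(r[seq_len(nd)]) - nd * (nd + 1) / 2) / (nd * nc)
}

# Wrap bare x/y/t vectors as a single-screen, all-valid recording.
as_recording <- function(x, y, t, screen = 1L, valid = TRUE,
                         g = screen_geometry()) {
  structure(list(participant_id = "t1",
                 samples = data.frame(t_ms = t, x_px = x, y_px = y,
                                      valid = rep_len(valid, length(x)),
                                      screen = rep_len(screen, length(x))),
                 geometry = g, layout_info = NULL),
            class = "gaze_recording")
}

# deterministic noise-free reader for ground-truth scanpath tests
clean_profile <- function(base = control_profile(), ...) {
  do.call(control_profile,
          utils::modifyList(list(p_skip_by_L = rep(0, 8),
                                 p_extra_fix_by_L = rep(0, 10),
                                 p_refix = 0, p_regress = 0, jitter_px = 0,
                                 blink_rate_per_min = 0), list(...)))
}

# memoised small cohort shared across test files (simulation + detection
# are deterministic, so computing it once is safe)
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$co)) {
    .fixture_env$co <- generate_cohort(8, 8, with_retest = FALSE, seed = 101)
  }
  .fixture_env$co
}
small_params <- function() {
  if (is.null(.fixture_env$params)) {
    .fixture_env$params <- cohort_parameters(small_cohort())
  }
  .fixture_env$params
}
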