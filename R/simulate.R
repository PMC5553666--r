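# Generative model of silent-reading scanpaths.
#
# The simulator is word-serial: the eye visits words in reading order, skips
# short words with a length-dependent probability, lands one or two first-pass
# fixations per word, occasionally steps back within the word (< 4 characters;
# the source of short backward "refixations") or regresses to an earlier word
# on the line, and sweeps back at line ends. Fixation durations are drawn from
# an ex-Gaussian distribution; each fixation is emitted as a run of 60 Hz gaze
# samples with Gaussian positional jitter. Blinks are inserted between
# fixations as runs of invalid samples.

#' Reader profile for scanpath simulation
#'
#' Parameters of the generative reading model for one reader (or one group's
#' default). Probability vectors are indexed by word length in characters
#' (index 1 = one-letter words; the last entry is reused for longer words).
#'
#' @param mu_fix,sigma_fix,tau_fix Ex-Gaussian fixation-duration parameters
#'   in ms (Gaussian mean and SD, exponential tail).
#' @param sacc_mean_chars,sacc_sd_chars Preferred forward-landing advance in
#'   characters; governs where the eye lands within the next word.
#' @param p_skip_by_L Per-length probability that a word is skipped
#'   (no first-pass fixation).
#' @param p_extra_fix_by_L Per-length probability of a second first-pass
#'   fixation on the word.
#' @param p_refix Per-fixation probability of a short (< 4 character) backward
#'   refixation step.
#' @param p_regress Per-word probability of a regression to an earlier word.
#' @param jitter_px SD of within-fixation gaze scatter in pixels; must stay
#'   well below the dispersion threshold.
#' @param blink_rate_per_min Blink rate (blinks are 100-300 ms invalid gaps).
#' @param min_fix_ms Floor applied to drawn fixation durations.
#' @return An object of class `reader_profile`.
#' @seealso [control_profile()], [dyslexic_profile()]
#' @export
reader_profile <- function(mu_fix, sigma_fix, tau_fix,
                           sacc_mean_chars, sacc_sd_chars,
                           p_skip_by_L, p_extra_fix_by_L,
                           p_refix, p_regress,
                           jitter_px = 3, blink_rate_per_min = 4.5,
                           min_fix_ms = 100) {
  p <- list(mu_fix = mu_fix, sigma_fix = sigma_fix, tau_fix = tau_fix,
            sacc_mean_chars = sacc_mean_chars, sacc_sd_chars = sacc_sd_chars,
            p_skip_by_L = p_skip_by_L, p_extra_fix_by_L = p_extra_fix_by_L,
            p_refix = p_refix, p_regress = p_regress,
            jitter_px = jitter_px, blink_rate_per_min = blink_rate_per_min,
            min_fix_ms = min_fix_ms)
  probs <- c(p$p_skip_by_L, p$p_extra_fix_by_L, p$p_refix, p$p_regress)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(p$mu_fix, p$sigma_fix, p$tau_fix) <= 0))
    stop("ex-Gaussian duration parameters must be positive")
  if (p$jitter_px < 0) stop("jitter_px must be nonnegative")
  structure(p, class = "reader_profile")
}

#' Default group reading profiles
#'
#' Calibrated defaults for the typical-reader (control) and dyslexic-reader
#' profiles. The dyslexic profile has a heavier fixation-duration tail,
#' shorter forward advances, less word skipping, more second first-pass
#' fixations, and more refixations and regressions, so that cohort-level
#' group differences reproduce the sign (and roughly the magnitude) of the
#' published control-minus-dyslexic contrasts, e.g. about 230 more fixations
#' and a ~90 ms larger tau in the dyslexic group on the basic text.
#'
#' @param ... Overrides passed to [reader_profile()].
#' @return A `reader_profile`.
#' @export
control_profile <- function(...) {
  defaults <- list(
    mu_fix = 180, sigma_fix = 40, tau_fix = 80,
    sacc_mean_chars = 7.5, sacc_sd_chars = 1.5,
    p_skip_by_L = c(0.60, 0.50, 0.40, 0.25, 0.15, 0.08, 0.05, 0.02),
    p_extra_fix_by_L = c(0.02, 0.02, 0.03, 0.08, 0.14, 0.25, 0.40, 0.55,
                         0.65, 0.75),
    p_refix = 0.10, p_regress = 0.05)
  do.call(reader_profile, utils::modifyList(defaults, list(...)))
}

#' @rdname control_profile
#' @export
dyslexic_profile <- function(...) {
  defaults <- list(
    mu_fix = 220, sigma_fix = 50, tau_fix = 170,
    sacc_mean_chars = 4.5, sacc_sd_chars = 1.5,
    p_skip_by_L = c(0.35, 0.28, 0.20, 0.10, 0.06, 0.03, 0.02, 0.01),
    p_extra_fix_by_L = c(0.12, 0.14, 0.18, 0.30, 0.45, 0.60, 0.72, 0.85,
                         0.90, 0.92),
    p_refix = 0.26, p_regress = 0.30)
  do.call(reader_profile, utils::modifyList(defaults, list(...)))
}

.p_at_L <- function(p_by_L, L) p_by_L[pmin(L, length(p_by_L))]

.draw_duration <- function(n, profile) {
  d <- rexgauss(n, profile$mu_fix, profile$sigma_fix, profile$tau_fix)
  pmax(d, profile$min_fix_ms)
}

#' Simulate one silent reading of a text
#'
#' Generates a 60 Hz gaze-sample stream for one reader reading `layout` once,
#' following the word-serial generative model described in the package
#' vignette. The returned recording carries the ground-truth event log
#' (planned fixations with their word indices and kinds, and inserted blinks)
#' as attributes, which downstream tests use as an oracle.
#'
#' @param layout A [build_layout()] / [radar_text()] layout.
#' @param profile A [reader_profile()].
#' @param seed Integer seed; the simulation is a deterministic function of
#'   (layout, profile, seed).
#' @param participant_id Identifier stored in the recording.
#' @return An object of class `gaze_recording`: list with `participant_id`,
#'   `samples` (data.frame: t_ms, x_px, y_px, valid, screen), `geometry`,
#'   `layout_info` (line width/spacing), and attributes `truth` (planned
#'   fixation log) and `blinks` (insertion log).
#' @export
simulate_reading <- function(layout, profile, seed, participant_id = "p1") {
  stopifnot(inherits(layout, "text_layout"), inherits(profile, "reader_profile"))
  g <- layout$geometry
  if (profile$jitter_px >= 45 / 2)
    stop("jitter_px too large relative to the dispersion window")
  with_local_seed(seed, {
    plan <- .plan_scanpath(layout, profile, g)
    .emit_samples(plan, profile, g, layout, participant_id)
  })
}

# Plan the fixation sequence: one row per fixation with target position,
# word index and kind (first_pass, refix, regress).
.plan_scanpath <- function(layout, profile, g) {
  b <- layout$boxes
  n_words <- nrow(b)
  cw <- g$px_per_char
  fx <- numeric(0); fy <- numeric(0); fw <- integer(0); kind <- character(0)
  fscreen <- integer(0)
  y_mid <- (b$y0 + b$y1) / 2

  add <- function(x, y, w, k, s) {
    fx[length(fx) + 1L] <<- x; fy[length(fy) + 1L] <<- y
    fw[length(fw) + 1L] <<- w; kind[length(kind) + 1L] <<- k
    fscreen[length(fscreen) + 1L] <<- s
  }

  line_key <- paste(b$screen, b$line)
  # geometric ground truth for a planned gaze position: the word box (with
  # half-character margins) under it on the given line, NA if off the line
  word_at <- function(xp, line) {
    wl <- which(line_key == line)
    cand <- wl[xp >= b$x0[wl] - 0.5 * cw & xp <= b$x1[wl] + 0.5 * cw]
    if (!length(cand)) return(NA_integer_)
    ctr <- (b$x0[cand] + b$x1[cand]) / 2
    cand[which.min(abs(ctr - xp))]
  }
  for (i in seq_len(n_words)) {
    L <- b$length_L[i]
    if (stats::runif(1) < .p_at_L(profile$p_skip_by_L, L)) next

    # landing position: advance into the word scaled by the preferred
    # forward step; long-advance readers land deeper into the word
    frac <- stats::rnorm(1, mean = 0.30 + 0.02 * profile$sacc_mean_chars,
                         sd = 0.08)
    frac <- min(max(frac, 0.10), 0.75)
    x1 <- b$x0[i] + frac * (b$x1[i] - b$x0[i])
    add(x1, y_mid[i], i, "first_pass", b$screen[i])
    if (stats::runif(1) < profile$p_refix) {
      xr <- x1 - stats::runif(1, 2.0, 3.9) * cw
      add(xr, y_mid[i], word_at(xr, line_key[i]), "refix", b$screen[i])
    }

    if (stats::runif(1) < .p_at_L(profile$p_extra_fix_by_L, L)) {
      step <- max(2.2 * cw, 0.45 * (b$x1[i] - b$x0[i]))
      x2 <- min(x1 + step, b$x1[i] + 0.4 * cw)
      add(x2, y_mid[i], i, "first_pass", b$screen[i])
      if (stats::runif(1) < profile$p_refix) {
        xr <- x2 - stats::runif(1, 2.0, 3.9) * cw
        add(xr, y_mid[i], word_at(xr, line_key[i]), "refix", b$screen[i])
      }
    }

    # regression: a long backward saccade to an earlier word on the line,
    # followed by a forward re-read of the intervening words
    if (stats::runif(1) < profile$p_regress) {
      same_line <- which(line_key == line_key[i] & seq_len(n_words) < i)
      same_line <- same_line[i - same_line <= 5 & i - same_line >= 2]
      same_line <- same_line[b$x0[i] - b$x0[same_line] >= 4 * cw]
      if (length(same_line) >= 1) {
        tgt <- same_line[sample.int(length(same_line), 1)]
        add((b$x0[tgt] + b$x1[tgt]) / 2, y_mid[tgt], tgt, "regress",
            b$screen[tgt])
        for (w in seq(tgt + 1L, i)) {  # re-read forward up to the launch word
          add((b$x0[w] + b$x1[w]) / 2, y_mid[w], w, "reread", b$screen[w])
        }
      }
    }
  }
  data.frame(x = fx, y = fy, word = fw, kind = kind, screen = fscreen,
             stringsAsFactors = FALSE)
}

# Emit gaze samples for a fixation plan: durations drawn ex-Gaussian, each
# fixation becomes round(duration/frame)+1 jittered samples; blinks are
# inserted between fixations as invalid runs.
.emit_samples <- function(plan, profile, g, layout, participant_id) {
  frame <- 1000 / g$sampling_hz
  n_fix <- nrow(plan)
  dur <- .draw_duration(n_fix, profile)
  n_samp <- pmax(round(dur / frame) + 1L, ceiling(90 / frame) + 1L)

  # choose blink insertion points from the expected reading time
  total_ms <- sum((n_samp - 1L) * frame)
  n_blinks <- stats::rpois(1, profile$blink_rate_per_min * total_ms / 60000)
  blink_after <- if (n_blinks > 0 && n_fix > 1)
    sort(sample(seq_len(n_fix - 1L), min(n_blinks, n_fix - 1L))) else integer(0)
  blink_len <- vapply(seq_along(blink_after), function(i)
    max(2L, as.integer(round(stats::runif(1, 100, 300) / frame))), integer(1))

  xs <- vector("list", n_fix); ys <- vector("list", n_fix)
  valid <- vector("list", n_fix); scr <- vector("list", n_fix)
  blink_log <- NULL
  for (i in seq_len(n_fix)) {
    k <- n_samp[i]
    xs[[i]] <- plan$x[i] + stats::rnorm(k, 0, profile$jitter_px)
    ys[[i]] <- plan$y[i] + stats::rnorm(k, 0, profile$jitter_px)
    valid[[i]] <- rep(TRUE, k)
    scr[[i]] <- rep(plan$screen[i], k)
    j <- match(i, blink_after)
    if (!is.na(j)) {
      bl <- blink_len[j]
      xs[[i]] <- c(xs[[i]], rep(NA_real_, bl))
      ys[[i]] <- c(ys[[i]], rep(NA_real_, bl))
      valid[[i]] <- c(valid[[i]], rep(FALSE, bl))
      scr[[i]] <- c(scr[[i]], rep(plan$screen[i], bl))
    }
  }
  x <- unlist(xs); y <- unlist(ys); v <- unlist(valid); s <- unlist(scr)
  t <- (seq_along(x) - 1L) * frame
  if (length(blink_after)) {
    starts <- cumsum(vapply(xs, length, integer(1)))  # index of last sample per block
    bstart <- t[starts[blink_after] - blink_len + 1L]
    blink_log <- data.frame(t_start_ms = bstart,
                            duration_ms = (blink_len - 1L) * frame,
                            n_samples = blink_len)
  }
  samples <- data.frame(t_ms = t, x_px = x, y_px = y, valid = v, screen = s)
  truth <- plan
  truth$duration_ms <- (n_samp - 1L) * frame
  rec <- structure(list(participant_id = participant_id, samples = samples,
                        geometry = g,
                        layout_info = list(
                          line_width_px = layout$line_width_px,
                          line_spacing_px = layout$line_spacing_px)),
                   class = "gaze_recording")
  attr(rec, "truth") <- truth
  attr(rec, "blinks") <- blink_log
  rec
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("Gaze recording '%s': %d samples (%.1f s), %d screens, %.0f%% valid\n",
              x$participant_id, nrow(x$samples),
              max(x$samples$t_ms) / 1000, length(unique(x$samples$screen)),
              100 * mean(x$samples$valid)))
  invisible(x)
}

#' Simulate a labelled reading cohort
#'
#' Generates test-session recordings for `n_control` typical and `n_dyslexic`
#' dyslexic readers (per-participant profiles are jittered around the group
#' defaults to create between-subject variation), plus an optional retest
#' session in which a subgroup of participants re-reads the text with the
#' same individual profile but fresh noise.
#'
#' @param n_control,n_dyslexic Group sizes.
#' @param layout Text layout (default: the built-in basic text).
#' @param with_retest Simulate a retest subgroup (defaults mirror the study
#'   design: up to 13 control and 22 dyslexic retest readers).
#' @param seed Master integer seed; the whole cohort is reproducible from it.
#' @param control,dyslexic Group default profiles.
#' @param between_sd Log-scale SD of between-subject jitter on the continuous
#'   profile parameters.
#' @param n_retest Named vector `c(control=, dyslexic=)` of retest sizes.
#' @return Object of class `reading_cohort`: list with `recordings` (named
#'   list of `gaze_recording`), `labels` (data.frame: participant_id, group,
#'   session), `layout`, `seed`.
#' @export
generate_cohort <- function(n_control = 37, n_dyslexic = 32,
                            layout = radar_text("basic")$layout,
                            with_retest = TRUE, seed = 1,
                            control = control_profile(),
                            dyslexic = dyslexic_profile(),
                            between_sd = 0.18,
                            n_retest = c(control = 13, dyslexic = 22)) {
  stopifnot(n_control >= 1, n_dyslexic >= 1)
  groups <- c(rep("control", n_control), rep("dyslexic", n_dyslexic))
  ids <- sprintf("%s%02d", ifelse(groups == "control", "c", "d"),
                 c(seq_len(n_control), seq_len(n_dyslexic)))

  with_local_seed(seed, {
    profiles <- lapply(seq_along(ids), function(i) {
      base <- if (groups[i] == "control") control else dyslexic
      .jitter_profile(base, between_sd)
    })
    rec_seeds <- sample.int(.Machine$integer.max - 1L, 2L * length(ids))
  })
  names(profiles) <- ids

  recs <- vector("list", 0)
  labels <- NULL
  for (i in seq_along(ids)) {
    rec <- simulate_reading(layout, profiles[[i]], seed = rec_seeds[i],
                            participant_id = ids[i])
    recs[[paste0(ids[i], ".test")]] <- rec
    labels <- rbind(labels, data.frame(participant_id = ids[i],
                                       group = groups[i], session = "test",
                                       stringsAsFactors = FALSE))
  }
  if (with_retest) {
    rt_ids <- c(ids[groups == "control"][seq_len(min(n_retest[["control"]], n_control))],
                ids[groups == "dyslexic"][seq_len(min(n_retest[["dyslexic"]], n_dyslexic))])
    for (id in rt_ids) {
      i <- match(id, ids)
      rec <- simulate_reading(layout, profiles[[id]],
                              seed = rec_seeds[length(ids) + i],
                              participant_id = id)
      recs[[paste0(id, ".retest")]] <- rec
      labels <- rbind(labels, data.frame(participant_id = id,
                                         group = groups[i], session = "retest",
                                         stringsAsFactors = FALSE))
    }
  }
  structure(list(recordings = recs, labels = labels, layout = layout,
                 seed = seed, profiles = profiles),
            class = "reading_cohort")
}

.jitter_profile <- function(base, between_sd) {
  j <- function(v, sd = between_sd) v * stats::rlnorm(length(v), 0, sd)
  jp <- function(p) pmin(j(p, 0.8 * between_sd), 0.97)
  reader_profile(
    mu_fix = j(base$mu_fix, 0.5 * between_sd),
    sigma_fix = j(base$sigma_fix, 0.5 * between_sd),
    tau_fix = j(base$tau_fix),
    sacc_mean_chars = j(base$sacc_mean_chars, 0.5 * between_sd),
    sacc_sd_chars = base$sacc_sd_chars,
    p_skip_by_L = jp(base$p_skip_by_L),
    p_extra_fix_by_L = jp(base$p_extra_fix_by_L),
    p_refix = jp(base$p_refix),
    p_regress = jp(base$p_regress),
    jitter_px = base$jitter_px,
    blink_rate_per_min = base$blink_rate_per_min,
    min_fix_ms = base$min_fix_ms)
}

#' @export
print.reading_cohort <- function(x, ...) {
  tab <- table(x$labels$group, x$labels$session)
  cat(sprintf("Reading cohort (seed %d): %d recordings\n", x$seed,
              nrow(x$labels)))
  print(tab)
  invisible(x)
}
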