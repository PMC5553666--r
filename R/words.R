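# Word-specific first-pass analysis: fixation-to-word assignment, word
# classes F0/F1/F>=2, control word norms, and gaze-difficulty counts X_L.

#' Assign fixations to words
#'
#' Maps each fixation to the word box it falls on: the word must be on the
#' same screen, on the vertically nearest text line (within half the line
#' spacing), and contain the fixation x-centre within its horizontal extent
#' extended by half a character width. Fixations between lines or words are
#' left unassigned (NA); they still count towards the total fixation number
#' but are ignored by the word analysis.
#'
#' @param fixations Output of [detect_fixations()].
#' @param layout A `text_layout`.
#' @param margin_chars Horizontal tolerance in character widths.
#' @return Integer vector (length = rows of `fixations`) of word indices into
#'   `layout$boxes`, NA when unassigned.
#' @export
assign_fixations_to_words <- function(fixations, layout, margin_chars = 0.5) {
  b <- layout$boxes
  margin <- margin_chars * layout$geometry$px_per_char
  y_mid <- (b$y0 + b$y1) / 2
  half_spacing <- layout$line_spacing_px / 2
  out <- rep(NA_integer_, nrow(fixations))
  if (nrow(fixations) == 0) return(out)
  # lines per screen, with their words
  for (i in seq_len(nrow(fixations))) {
    on_screen <- which(b$screen == fixations$screen[i])
    if (!length(on_screen)) next
    dy <- abs(y_mid[on_screen] - fixations$cy[i])
    lines <- unique(b$line[on_screen])
    line_dy <- vapply(lines, function(l)
      min(dy[b$line[on_screen] == l]), numeric(1))
    best_line <- lines[which.min(line_dy)]
    if (min(line_dy) > half_spacing) next
    cand <- on_screen[b$line[on_screen] == best_line]
    hit <- cand[fixations$cx[i] >= b$x0[cand] - margin &
                  fixations$cx[i] <= b$x1[cand] + margin]
    if (!length(hit)) next
    if (length(hit) > 1) {
      mid <- (b$x0[hit] + b$x1[hit]) / 2
      hit <- hit[which.min(abs(mid - fixations$cx[i]))]
    }
    out[i] <- hit
  }
  out
}

#' First-pass analysis of an assigned fixation stream
#'
#' The first pass on a word is the maximal run of consecutive fixations on
#' that word starting at its first visit; its gaze duration is the summed
#' fixation time of that run. Each later maximal run on the same word counts
#' as one revisit. Unassigned fixations are dropped before runs are formed.
#' Word classes: F0 = words never fixated, F1 = one first-pass fixation,
#' Fge2 = two or more first-pass fixations; F0 + F1 + Fge2 equals the word
#' count of the layout.
#'
#' @param word_idx Integer word assignment per fixation
#'   ([assign_fixations_to_words()]), NA allowed.
#' @param durations Fixation durations (ms), parallel to `word_idx`.
#' @param n_words Total words in the layout.
#' @return List with `visits` (data.frame: word_idx, first_pass_gaze,
#'   first_pass_fix_count, revisits — one row per word) and `counts`
#'   (named: F0, F1, Fge2).
#' @export
first_pass_analysis <- function(word_idx, durations, n_words) {
  stopifnot(length(word_idx) == length(durations))
  keep <- !is.na(word_idx)
  w <- word_idx[keep]; d <- durations[keep]
  gaze <- numeric(n_words); nfix <- integer(n_words); revis <- integer(n_words)
  seen <- logical(n_words)
  if (length(w)) {
    r <- rle(w)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      wi <- r$values[k]
      if (!seen[wi]) {
        seen[wi] <- TRUE
        gaze[wi] <- sum(d[starts[k]:ends[k]])
        nfix[wi] <- r$lengths[k]
      } else {
        revis[wi] <- revis[wi] + 1L
      }
    }
  }
  counts <- c(F0 = sum(!seen), F1 = sum(nfix == 1L), Fge2 = sum(nfix >= 2L))
  list(visits = data.frame(word_idx = seq_len(n_words),
                           first_pass_gaze = gaze,
                           first_pass_fix_count = nfix,
                           revisits = revis),
       counts = counts)
}

#' Control-population word norms
#'
#' Per-word mean and SD of first-pass gaze duration over the control readers
#' who fixated the word (skips are excluded). Words fixated by fewer than two
#' controls get no norm (NA) and are not scored.
#'
#' @param control_visits List of `visits` data.frames
#'   (from [first_pass_analysis()]), one per control participant.
#' @return data.frame: word_idx, mean_gaze, sd_gaze, n_contributing.
#' @export
build_control_norms <- function(control_visits) {
  G <- .gaze_matrix(control_visits)
  .norms_from_matrix(G)
}

# rows = participants, cols = words; NA where the word was skipped
.gaze_matrix <- function(visit_list) {
  n_words <- nrow(visit_list[[1]])
  G <- do.call(rbind, lapply(visit_list, function(v) {
    g <- v$first_pass_gaze
    g[v$first_pass_fix_count == 0] <- NA
    g
  }))
  colnames(G) <- seq_len(n_words)
  G
}

.norms_from_matrix <- function(G, exclude_row = NULL) {
  if (!is.null(exclude_row)) G <- G[-exclude_row, , drop = FALSE]
  n <- colSums(!is.na(G))
  m <- ifelse(n >= 2, colMeans(G, na.rm = TRUE), NA_real_)
  s <- ifelse(n >= 2, apply(G, 2, stats::sd, na.rm = TRUE), NA_real_)
  data.frame(word_idx = seq_len(ncol(G)), mean_gaze = m, sd_gaze = s,
             n_contributing = n)
}

#' Gaze-difficulty counts by word length
#'
#' Scores each fixated word by the Gaussian cumulative probability of the
#' participant's first-pass gaze duration under the control norm for that
#' word; words scoring strictly above `cutoff` are counted into the length
#' bin of the word. Skipped words and words without a norm contribute
#' nothing.
#'
#' @param visits `visits` data.frame for one participant.
#' @param norms [build_control_norms()] output.
#' @param layout The `text_layout` (provides word lengths).
#' @param bins Named list of `c(min_L, max_L)` length ranges
#'   (see [radar_text()]).
#' @param cutoff Score threshold (strict).
#' @return Named integer vector of X counts, one per bin.
#' @export
gaze_difficulty_counts <- function(visits, norms, layout, bins,
                                   cutoff = 0.9) {
  L <- layout$boxes$length_L
  fixated <- visits$first_pass_fix_count > 0
  ok <- fixated & !is.na(norms$mean_gaze) & !is.na(norms$sd_gaze) &
    norms$sd_gaze > 0
  score <- rep(NA_real_, nrow(visits))
  score[ok] <- stats::pnorm(visits$first_pass_gaze[ok],
                            norms$mean_gaze[ok], norms$sd_gaze[ok])
  flagged <- !is.na(score) & score > cutoff
  vapply(bins, function(rng) {
    sum(flagged & L >= rng[1] & L <= rng[2])
  }, integer(1))
}
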