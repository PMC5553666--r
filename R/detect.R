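# Dispersion-threshold (I-DT) fixation detection and saccade extraction.

#' Detection configuration
#'
#' Thresholds of the dispersion fixation detector and the saccade speed
#' criterion: gaze points constitute a fixation when they remain within a
#' `d_max`-pixel window for at least `t_min` ms; an inter-fixation transition
#' is recognised as a saccade only when its speed exceeds `speed_min` deg/s.
#'
#' @param t_min Minimum fixation duration in ms.
#' @param d_max Maximum gaze-point scatter (box dispersion) in pixels;
#'   45 px corresponds to 1.5 degrees on the default screen.
#' @param speed_min Minimum saccade speed in degrees/second.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(t_min = 90, d_max = 45, speed_min = 100) {
  stopifnot(t_min > 0, d_max > 0, speed_min > 0)
  structure(list(t_min = t_min, d_max = d_max, speed_min = speed_min),
            class = "detection_config")
}

#' Identify blink intervals in a recording
#'
#' Blinks appear as runs of invalid gaze samples; maximal runs of at least
#' two consecutive invalid frames are reported as blink intervals and are
#' excluded from fixation clustering (a blink terminates the current
#' dispersion window). Isolated single invalid samples are treated as dropped
#' frames and skipped without interrupting a fixation.
#'
#' @param rec A `gaze_recording`.
#' @return data.frame with columns t_start_ms, t_end_ms, duration_ms,
#'   n_samples (zero rows if there are no blinks).
#' @export
detect_blinks <- function(rec) {
  s <- rec$samples
  r <- rle(!s$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  data.frame(t_start_ms = s$t_ms[starts[keep]],
             t_end_ms = s$t_ms[ends[keep]],
             duration_ms = s$t_ms[ends[keep]] - s$t_ms[starts[keep]],
             n_samples = r$lengths[keep])
}

# Core I-DT pass over one uninterrupted run of valid samples.
# Window dispersion is max(x-range, y-range); a window is emitted once its
# time span reaches t_min, then grown greedily while dispersion stays within
# d_max (first-fit, left to right).
.idt_segment <- function(x, y, t, t_min, d_max) {
  n <- length(x)
  out_cx <- numeric(0); out_cy <- numeric(0); out_t0 <- numeric(0)
  out_dur <- numeric(0); out_n <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && t[j] - t[i] < t_min) j <- j + 1L
    if (t[j] - t[i] < t_min) break
    xw <- x[i:j]; yw <- y[i:j]
    xmin <- min(xw); xmax <- max(xw); ymin <- min(yw); ymax <- max(yw)
    if (max(xmax - xmin, ymax - ymin) > d_max) {
      i <- i + 1L
      next
    }
    while (j < n) {
      nx <- x[j + 1L]; ny <- y[j + 1L]
      nxmin <- min(xmin, nx); nxmax <- max(xmax, nx)
      nymin <- min(ymin, ny); nymax <- max(ymax, ny)
      if (max(nxmax - nxmin, nymax - nymin) > d_max) break
      xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      j <- j + 1L
    }
    k <- length(out_cx) + 1L
    out_cx[k] <- mean(x[i:j]); out_cy[k] <- mean(y[i:j])
    out_t0[k] <- t[i]; out_dur[k] <- t[j] - t[i]; out_n[k] <- j - i + 1L
    i <- j + 1L
  }
  data.frame(cx = out_cx, cy = out_cy, t_start = out_t0,
             duration = out_dur, n_samples = out_n)
}

#' Detect fixations with the dispersion algorithm
#'
#' Clusters valid gaze samples into fixations with a moving-window dispersion
#' (I-DT) procedure: a window is grown while its spatial dispersion stays
#' within `cfg$d_max`; windows spanning at least `cfg$t_min` are emitted as
#' fixations located at the cloud centroid, with duration the time the gaze
#' stayed inside the window. Blinks and screen changes terminate windows;
#' fixations are never merged across them.
#'
#' @param rec A `gaze_recording`.
#' @param cfg A [detection_config()].
#' @return data.frame of fixations: cx, cy, t_start, duration, n_samples,
#'   screen, segment (index of the blink/screen-delimited run the fixation
#'   came from).
#' @export
detect_fixations <- function(rec, cfg = detection_config()) {
  s <- rec$samples
  if (nrow(s) == 0) {
    return(data.frame(cx = numeric(0), cy = numeric(0), t_start = numeric(0),
                      duration = numeric(0), n_samples = integer(0),
                      screen = integer(0), segment = integer(0)))
  }
  # segment boundaries: blinks (>= 2 invalid frames) and screen changes
  r <- rle(!s$valid)
  blink <- rep(r$values & r$lengths >= 2L, r$lengths)
  seg_id <- cumsum(c(TRUE, blink[-1] != blink[-nrow(s)] |
                       s$screen[-1] != s$screen[-nrow(s)]))
  out <- NULL
  seg_count <- 0L
  for (seg in split(seq_len(nrow(s)), seg_id)) {
    if (blink[seg[1]]) next
    seg_count <- seg_count + 1L
    idx <- seg[s$valid[seg]]  # drop isolated invalid frames
    if (length(idx) < 2) next
    f <- .idt_segment(s$x_px[idx], s$y_px[idx], s$t_ms[idx],
                      cfg$t_min, cfg$d_max)
    if (nrow(f)) {
      f$screen <- s$screen[idx[1]]
      f$segment <- seg_count
      out <- rbind(out, f)
    }
  }
  if (is.null(out)) {
    out <- data.frame(cx = numeric(0), cy = numeric(0), t_start = numeric(0),
                      duration = numeric(0), n_samples = integer(0),
                      screen = integer(0), segment = integer(0))
  }
  out
}

#' Extract saccades between consecutive fixations
#'
#' One candidate movement per consecutive fixation pair within the same
#' uninterrupted segment (pairs spanning a blink or a screen change produce
#' no saccade). Length is the signed difference of the fixation centres along
#' the x-axis; speed is the Euclidean displacement in degrees divided by the
#' inter-fixation gap. Candidates are retained as saccades only when speed
#' exceeds `cfg$speed_min`; slower transitions are dropped from saccade
#' statistics without merging the fixations. Line-return sweeps are flagged
#' when the movement is strongly leftward (more than 60% of the line width)
#' and the gaze drops by at least half the line spacing.
#'
#' @param fixations Output of [detect_fixations()].
#' @param cfg A [detection_config()].
#' @param g A [screen_geometry()].
#' @param line_width_px,line_spacing_px Text-line geometry used for the
#'   line-return flag.
#' @return data.frame of saccades: idx_from, length_x, distance, gap, speed,
#'   is_line_return, is_backward.
#' @export
extract_saccades <- function(fixations, cfg = detection_config(),
                             g = screen_geometry(),
                             line_width_px = 42 * g$px_per_char,
                             line_spacing_px = 76) {
  empty <- data.frame(idx_from = integer(0), length_x = numeric(0),
                      distance = numeric(0), gap = numeric(0),
                      speed = numeric(0), is_line_return = logical(0),
                      is_backward = logical(0))
  n <- nrow(fixations)
  if (n < 2) return(empty)
  i <- seq_len(n - 1L)
  same_seg <- fixations$segment[i] == fixations$segment[i + 1L]
  dx <- fixations$cx[i + 1L] - fixations$cx[i]
  dy <- fixations$cy[i + 1L] - fixations$cy[i]
  gap <- fixations$t_start[i + 1L] -
    (fixations$t_start[i] + fixations$duration[i])
  dist <- sqrt(dx^2 + dy^2)
  speed <- ifelse(gap > 0, px_to_deg(dist, g) / (gap / 1000), Inf)
  keep <- same_seg & gap > 0 & speed > cfg$speed_min
  out <- data.frame(idx_from = i[keep], length_x = dx[keep],
                    distance = dist[keep], gap = gap[keep],
                    speed = speed[keep],
                    is_line_return = dx[keep] < -0.6 * line_width_px &
                      dy[keep] >= line_spacing_px / 2,
                    is_backward = dx[keep] < 0)
  out
}
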