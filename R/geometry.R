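#' Screen geometry for a reading display
#'
#' Bundles the display properties needed to convert between pixels, degrees of
#' visual angle and character units on a monospaced reading display. Defaults
#' describe an 18.5-inch 1366 x 768 monitor viewed at 50 cm, spanning 46.4
#' degrees horizontally, sampled by a 60 Hz gaze tracker, with a character
#' width of 24.75 px (a 2-character step subtends 1.65 degrees).
#'
#' @param width_px Screen width in pixels.
#' @param height_px Screen height in pixels.
#' @param width_deg Horizontal extent of the screen in degrees of visual angle.
#' @param sampling_hz Gaze sampling rate in Hz.
#' @param px_per_char Width of one character cell in pixels.
#' @return An object of class `screen_geometry`.
#' @examples
#' g <- screen_geometry()
#' px_to_deg(100, g)  # ~3.4 degrees
#' @export
screen_geometry <- function(width_px = 1366, height_px = 768,
                            width_deg = 46.4, sampling_hz = 60,
                            px_per_char = 24.75) {
  stopifnot(width_px > 0, height_px > 0, width_deg > 0,
            sampling_hz > 0, px_per_char > 0)
  structure(list(width_px = width_px, height_px = height_px,
                 width_deg = width_deg, sampling_hz = sampling_hz,
                 px_per_char = px_per_char,
                 px_per_deg = width_px / width_deg),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("Screen: %d x %d px, %.1f deg wide (%.2f px/deg), %g Hz, %.2f px/char\n",
              x$width_px, x$height_px, x$width_deg, x$px_per_deg,
              x$sampling_hz, x$px_per_char))
  invisible(x)
}

#' Convert pixels to degrees of visual angle
#'
#' Linear small-angle conversion using the horizontal px/deg scale of the
#' screen; the same scale is used vertically (square pixels).
#'
#' @param d Displacement in pixels (signed values allowed).
#' @param g A [screen_geometry()].
#' @return Degrees of visual angle, same sign as `d`.
#' @export
px_to_deg <- function(d, g = screen_geometry()) {
  if (!all(is.finite(d))) stop("non-finite pixel input")
  d / g$px_per_deg
}

#' Convert degrees of visual angle to pixels
#' @inheritParams px_to_deg
#' @param a Angle in degrees.
#' @export
deg_to_px <- function(a, g = screen_geometry()) {
  if (!all(is.finite(a))) stop("non-finite angle input")
  a * g$px_per_deg
}

#' Convert pixels to character units
#'
#' @inheritParams px_to_deg
#' @return Displacement in character widths (not rounded).
#' @export
px_to_chars <- function(d, g = screen_geometry()) {
  if (!all(is.finite(d))) stop("non-finite pixel input")
  d / g$px_per_char
}

#' Convert character units to pixels
#' @inheritParams px_to_deg
#' @param ch Displacement in character widths.
#' @export
chars_to_px <- function(ch, g = screen_geometry()) {
  if (!all(is.finite(ch))) stop("non-finite character input")
  ch * g$px_per_char
}

#' Build a monospaced word-box layout from raw text
#'
#' Tokenises `text` on whitespace and lays the words out on a monospaced
#' grid: words are wrapped greedily into lines of at most `max_line_chars`
#' characters, lines are grouped into screens of `lines_per_screen`, and each
#' word receives a pixel bounding box. The layout is the geometric ground
#' truth against which fixations are assigned to words.
#'
#' @param text A single string; words are whitespace-delimited tokens.
#' @param g A [screen_geometry()].
#' @param lines_per_screen Lines displayed per screen.
#' @param max_line_chars Maximum characters (including inter-word spaces) per line.
#' @param margin_left_px,margin_top_px Top-left corner of the text block.
#' @param line_spacing_px Vertical distance between line tops.
#' @param char_height_px Height of a character cell (the word box height).
#' @return An object of class `text_layout`: list with `geometry`, `boxes`
#'   (data.frame: word, length_L, screen, line, x0, x1, y0, y1), `n_screens`,
#'   `line_spacing_px`, `line_width_px`.
#' @examples
#' lay <- build_layout("the cat sat on the mat")
#' layout_stats(lay)
#' @export
build_layout <- function(text, g = screen_geometry(), lines_per_screen = 6,
                         max_line_chars = 42, margin_left_px = 120,
                         margin_top_px = 120, line_spacing_px = 76,
                         char_height_px = 33) {
  stopifnot(is.character(text), length(text) == 1)
  words <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(words) == 0 || !nzchar(text)) stop("empty text")
  L <- nchar(words)

  # greedy wrap: word + following space must fit within max_line_chars
  line <- integer(length(words))
  col <- integer(length(words))   # 0-based starting column on the line
  cur_line <- 1L; cur_col <- 0L
  for (i in seq_along(words)) {
    need <- L[i]
    if (cur_col > 0 && cur_col + 1 + need > max_line_chars) {
      cur_line <- cur_line + 1L
      cur_col <- 0L
    } else if (cur_col > 0) {
      cur_col <- cur_col + 1L  # inter-word space
    }
    line[i] <- cur_line
    col[i] <- cur_col
    cur_col <- cur_col + need
  }
  screen <- (line - 1L) %/% lines_per_screen + 1L
  line_on_screen <- (line - 1L) %% lines_per_screen + 1L

  x0 <- margin_left_px + col * g$px_per_char
  x1 <- x0 + L * g$px_per_char
  y0 <- margin_top_px + (line_on_screen - 1L) * line_spacing_px
  y1 <- y0 + char_height_px
  boxes <- data.frame(word = words, length_L = L, screen = screen,
                      line = line_on_screen, x0 = x0, x1 = x1, y0 = y0, y1 = y1,
                      stringsAsFactors = FALSE)
  structure(list(geometry = g, boxes = boxes,
                 n_screens = max(screen),
                 line_spacing_px = line_spacing_px,
                 line_width_px = max_line_chars * g$px_per_char),
            class = "text_layout")
}

#' Summary statistics of a text layout
#'
#' @param layout A [build_layout()] result.
#' @return List: word_count, unique_words, chars_with_spaces,
#'   chars_without_spaces, mean_chars_per_word, sentence_count (words ending
#'   in sentence punctuation), n_screens, n_lines.
#' @export
layout_stats <- function(layout) {
  b <- layout$boxes
  chars <- sum(b$length_L)
  # one space between adjacent words on the same line
  spaces <- sum(unlist(lapply(split(seq_len(nrow(b)),
                                    interaction(b$screen, b$line, drop = TRUE)),
                              function(i) length(i) - 1L)))
  list(word_count = nrow(b),
       unique_words = length(unique(b$word)),
       chars_with_spaces = chars + spaces,
       chars_without_spaces = chars,
       mean_chars_per_word = chars / nrow(b),
       sentence_count = sum(grepl("[.!;?]$", b$word)),
       n_screens = layout$n_screens,
       n_lines = length(unique(paste(b$screen, b$line))))
}

#' @export
print.text_layout <- function(x, ...) {
  s <- layout_stats(x)
  cat(sprintf("Text layout: %d words (%d unique) on %d screens, mean %.2f chars/word\n",
              s$word_count, s$unique_words, s$n_screens, s$mean_chars_per_word))
  invisible(x)
}

#' Write / read a layout as JSON
#'
#' @param layout A `text_layout`.
#' @param path File path.
#' @export
write_layout_json <- function(layout, path) {
  obj <- list(geometry = layout$geometry[c("width_px", "height_px", "width_deg",
                                           "sampling_hz", "px_per_char")],
              line_spacing_px = layout$line_spacing_px,
              line_width_px = layout$line_width_px,
              boxes = layout$boxes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- do.call(screen_geometry, as.list(obj$geometry))
  boxes <- as.data.frame(obj$boxes, stringsAsFactors = FALSE)
  structure(list(geometry = g, boxes = boxes,
                 n_screens = max(boxes$screen),
                 line_spacing_px = obj$line_spacing_px,
                 line_width_px = obj$line_width_px),
            class = "text_layout")
}
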