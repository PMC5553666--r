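# Built-in synthetic reading texts.
#
# The screening protocol is defined relative to a reading text with known
# statistics: a "basic" text of 181 words (mean 5.4 characters/word, five
# screens of up to six double-spaced lines) and an "easy" text of 143 shorter
# words. The original Greek stimuli are not distributed; these generators
# produce synthetic pseudo-word texts whose word-count, word-length profile
# and screen layout match the published statistics, which is all the geometry
# the pipeline depends on.

# word-length multiset of the basic text: 181 words, mean ~5.4 chars
.basic_length_counts <- c(`1` = 6, `2` = 13, `3` = 24, `4` = 27, `5` = 28,
                          `6` = 25, `7` = 21, `8` = 17, `9` = 10, `10` = 6,
                          `11` = 3, `12` = 1)
# easy text: 143 words, mean ~4.2 chars
.easy_length_counts <- c(`1` = 10, `2` = 17, `3` = 26, `4` = 30, `5` = 26,
                         `6` = 16, `7` = 9, `8` = 6, `9` = 2, `10` = 1)

.make_pseudo_text <- function(length_counts, seed) {
  lengths <- rep(as.integer(names(length_counts)), length_counts)
  with_local_seed(seed, {
    lengths <- sample(lengths)
    vapply(lengths, function(L) {
      paste(sample(letters, L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

#' Built-in reading-text configurations
#'
#' Returns the layout and word-length bin definition for one of the two
#' built-in synthetic texts. The `basic` text has 181 words over 5 screens
#' and uses difficulty bins L<=3, L=4-5, L=6-7, L>=8; the `easy` text has 143
#' shorter words and uses bins L<=3, L=4, L=5, L>=6. The pseudo-word content
#' is deterministic (fixed internal seed) so layouts are reproducible.
#'
#' @param text `"basic"` or `"easy"`.
#' @param g A [screen_geometry()].
#' @return List with elements `layout` (a `text_layout`), `bins` (named list
#'   of `c(min_L, max_L)` ranges) and `name`.
#' @examples
#' cfg <- radar_text("basic")
#' layout_stats(cfg$layout)$word_count  # 181
#' @export
radar_text <- function(text = c("basic", "easy"), g = screen_geometry()) {
  text <- match.arg(text)
  words <- if (text == "basic") .make_pseudo_text(.basic_length_counts, 20170811)
           else .make_pseudo_text(.easy_length_counts, 20170812)
  bins <- radar_text_bins(text)
  layout <- build_layout(paste(words, collapse = " "), g = g,
                         lines_per_screen = 6, max_line_chars = 42)
  list(layout = layout, bins = bins, name = text)
}

# Evaluate .Random.seed-preserving code under a fixed seed.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
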