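# General (non-word-specific) reading parameters: ex-Gaussian tau, saccade
# quartiles, short backward refixations, total fixation count.

#' Saccade-length quartiles
#'
#' Empirical quartiles (linear CDF interpolation, R quantile type 7) of the
#' signed x-axis saccade lengths, excluding line-return sweeps.
#'
#' @param saccades Output of [extract_saccades()].
#' @return Named numeric: q25, q50, q75 (pixels).
#' @export
saccade_quartiles <- function(saccades) {
  x <- saccades$length_x[!saccades$is_line_return]
  if (length(x) < 4) stop("need at least 4 saccades")
  stats::setNames(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE,
                                  type = 7),
                  c("q25", "q50", "q75"))
}

#' Count short backward refixations
#'
#' Number of backward saccades shorter than `threshold_px` along the x-axis
#' (line-return sweeps excluded); with the default 100 px threshold
#' (4 characters) these are predominantly within-word backward movements.
#'
#' @param saccades Output of [extract_saccades()].
#' @param threshold_px Strict upper bound on |length_x| in pixels.
#' @return Integer count R.
#' @export
count_refixations <- function(saccades, threshold_px = 100) {
  stopifnot(threshold_px > 0)
  sum(saccades$is_backward & !saccades$is_line_return &
        abs(saccades$length_x) < threshold_px)
}

#' Total fixation count
#'
#' @param fixations Output of [detect_fixations()].
#' @return Integer Fix: total fixations across all screens.
#' @export
count_fixations <- function(fixations) nrow(fixations)
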