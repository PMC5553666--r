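# Plain-text I/O: gaze CSV, cohort manifest, layout JSON (see geometry.R).
#
# Gaze CSV column contract (exact): participant_id, screen, t_ms, x_px,
# y_px, valid (0/1). One file per session.

#' Write recordings to a gaze CSV
#'
#' @param recordings A single `gaze_recording` or a list of them.
#' @param path Output file.
#' @export
write_gaze_csv <- function(recordings, path) {
  if (inherits(recordings, "gaze_recording")) recordings <- list(recordings)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))  # lossless
  tab <- do.call(rbind, lapply(recordings, function(r) {
    data.frame(participant_id = r$participant_id,
               screen = r$samples$screen,
               t_ms = fmt(r$samples$t_ms),
               x_px = fmt(r$samples$x_px),
               y_px = fmt(r$samples$y_px),
               valid = as.integer(r$samples$valid),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read recordings from a gaze CSV
#'
#' Validates the exact column contract and the within-participant timestamp
#' order; violations are reported with the first offending (1-based data)
#' line number.
#'
#' @param path Input CSV.
#' @param g A [screen_geometry()] to attach to the recordings.
#' @return Named list of `gaze_recording` objects (participant order of
#'   first appearance).
#' @export
read_gaze_csv <- function(path, g = screen_geometry()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  wanted <- c("participant_id", "screen", "t_ms", "x_px", "y_px", "valid")
  if (!identical(sort(colnames(tab)), sort(wanted)))
    stop("gaze CSV must have exactly the columns: ",
         paste(wanted, collapse = ", "))
  bad <- which(!tab$valid %in% c(0L, 1L))
  if (length(bad))
    stop("invalid `valid` flag at line ", bad[1])
  ids <- unique(tab$participant_id)
  recs <- lapply(ids, function(id) {
    rows <- which(tab$participant_id == id)
    t <- tab$t_ms[rows]
    nm <- which(diff(t) <= 0)
    if (length(nm))
      stop("non-monotone timestamps for participant ", id,
           " at line ", rows[nm[1] + 1L])
    structure(list(participant_id = id,
                   samples = data.frame(t_ms = t,
                                        x_px = tab$x_px[rows],
                                        y_px = tab$y_px[rows],
                                        valid = tab$valid[rows] == 1L,
                                        screen = tab$screen[rows]),
                   geometry = g, layout_info = NULL),
              class = "gaze_recording")
  })
  stats::setNames(recs, ids)
}

#' Write / read a cohort manifest (labels) CSV
#'
#' Columns: participant_id, group, session.
#'
#' @param labels data.frame of labels (as in a `reading_cohort`).
#' @param path File path.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "group", "session")
  if (!all(needed %in% colnames(tab)))
    stop("labels CSV must have columns: ", paste(needed, collapse = ", "))
  if (!all(tab$group %in% c("control", "dyslexic")))
    stop("group must be 'control' or 'dyslexic'")
  tab[needed]
}

#' Write a whole cohort to plain-text files
#'
#' Writes one gaze CSV per session, the layout JSON and the labels CSV into
#' a directory, and reads them back into a `reading_cohort`.
#'
#' @param cohort A `reading_cohort`.
#' @param dir Output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ses in unique(cohort$labels$session)) {
    ids <- cohort$labels$participant_id[cohort$labels$session == ses]
    recs <- cohort$recordings[paste0(ids, ".", ses)]
    write_gaze_csv(recs, file.path(dir, paste0("gaze_", ses, ".csv")))
  }
  write_layout_json(cohort$layout, file.path(dir, "layout.json"))
  write_labels_csv(cohort$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  labels <- read_labels_csv(file.path(dir, "labels.csv"))
  layout <- read_layout_json(file.path(dir, "layout.json"))
  recordings <- list()
  for (ses in unique(labels$session)) {
    recs <- read_gaze_csv(file.path(dir, paste0("gaze_", ses, ".csv")),
                          g = layout$geometry)
    for (id in names(recs)) {
      recs[[id]]$layout_info <- list(line_width_px = layout$line_width_px,
                                     line_spacing_px = layout$line_spacing_px)
      recordings[[paste0(id, ".", ses)]] <- recs[[id]]
    }
  }
  structure(list(recordings = recordings, labels = labels, layout = layout,
                 seed = NA_integer_),
            class = "reading_cohort")
}
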