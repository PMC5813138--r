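#' Construct and validate an event table
#'
#' One row per event: `cue` rows mark cue presentations (no response), the
#' three target conditions carry the trial's reaction time and an accuracy
#' flag.  Onsets must be strictly increasing and every response must finish
#' inside the run.
#'
#' @param onset Event onsets in seconds from run start.
#' @param duration Event durations in seconds (0 for impulse events).
#' @param trial_type Character, one of `"cue"`, `"congruent"`,
#'   `"easy_incongruent"`, `"hard_incongruent"`.
#' @param response_time Reaction times in milliseconds (`NA` for cues).
#' @param accuracy 0/1 correctness flag (`NA` for cues).
#' @param run_duration Optional run length in seconds for bounds checking.
#' @return A `data.frame` with the five columns above, class `event_table`.
#' @export
event_table <- function(onset, duration, trial_type, response_time,
                        accuracy, run_duration = NULL) {
  ev <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   trial_type = as.character(trial_type),
                   response_time = as.numeric(response_time),
                   accuracy = as.numeric(accuracy),
                   stringsAsFactors = FALSE)
  known <- c("cue", event_conditions(), "error")
  bad <- setdiff(unique(ev$trial_type), known)
  if (length(bad))
    stop("unknown trial_type values: ", paste(bad, collapse = ", "))
  if (any(diff(ev$onset) <= 0))
    stop("event onsets must be strictly increasing")
  if (!is.null(run_duration)) {
    tgt <- ev$trial_type %in% event_conditions()
    ends <- ev$onset + ifelse(is.na(ev$response_time), 0,
                              ev$response_time / 1000)
    if (any(ev$onset < 0) || any(ends[tgt] >= run_duration))
      stop("events (onset + response time) must lie within the run")
  }
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Target condition labels
#'
#' The three flanker conditions, ordered by difficulty.
#' @return Character vector of length 3.
#' @export
event_conditions <- function() {
  c("congruent", "easy_incongruent", "hard_incongruent")
}

#' Read / write BIDS-style event tables
#'
#' Tab-separated with the exact column set
#' `onset, duration, trial_type, response_time, accuracy`.
#'
#' @param path File path (`*_events.tsv`).
#' @return `read_events_tsv()` returns an [event_table()].
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", "n/a"))
  need <- c("onset", "duration", "trial_type", "response_time", "accuracy")
  if (!all(need %in% names(ev)))
    stop("events file must have columns: ", paste(need, collapse = ", "))
  event_table(ev$onset, ev$duration, ev$trial_type,
              ev$response_time, ev$accuracy)
}

#' @rdname read_events_tsv
#' @param events An [event_table()].
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write rigid-body motion traces
#'
#' Six whitespace-delimited columns per volume: x, y, z translations in mm
#' and pitch, roll, yaw rotations in degrees.
#'
#' @param path File path.
#' @return `read_motion()` returns a numeric matrix (volumes x 6) with
#'   column names `x, y, z, pitch, roll, yaw`.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) stop("motion file must have exactly 6 columns")
  colnames(m) <- c("x", "y", "z", "pitch", "roll", "yaw")
  m
}

#' @rdname read_motion
#' @param motion Volumes x 6 numeric matrix.
#' @export
write_motion <- function(motion, path) {
  stopifnot(ncol(motion) == 6)
  utils::write.table(motion, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
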