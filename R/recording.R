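#' EEG recordings and event segments
#'
#' A `recording` couples a channels-by-time signal matrix (microvolts) with
#' its sampling rate, an [event_table()] and cohort bookkeeping (participant
#' and run identifiers). A `segment` is a slice of one recording attributed
#' to a (participant, task, event) cell of the study design.
#'
#' @param signal Numeric matrix, channels x time.
#' @param sampling_rate Samples per second (160 for the reference dataset).
#' @param events An [event_table()].
#' @param participant_id Integer participant label.
#' @param run_id Integer run number (1..14 in the reference protocol).
#' @param channels A [channel_map()]; `NULL` skips montage validation for
#'   non-standard channel counts.
#' @return An object of class `recording`.
#' @export
recording <- function(signal, sampling_rate, events = event_table(),
                      participant_id = NA_integer_, run_id = NA_integer_,
                      channels = channel_map()) {
  signal <- as.matrix(signal)
  if (!is.null(channels)) {
    validate_channel_map(channels)
    if (nrow(signal) != length(channels)) {
      stop("recording: signal has ", nrow(signal),
           " rows but the montage has ", length(channels), " channels")
    }
    rownames(signal) <- as.character(channels)
  }
  if (sampling_rate <= 0) stop("recording: sampling_rate must be positive")
  if (nrow(events) > 0L && max(event_end(events)) > ncol(signal)) {
    stop("recording: event span exceeds signal length")
  }
  structure(
    list(signal = signal, sampling_rate = sampling_rate, events = events,
         participant_id = as.integer(participant_id),
         run_id = as.integer(run_id), channels = channels),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> participant %s, run %s: %d channels x %d samples @ %g Hz, %d events\n",
              x$participant_id, x$run_id, nrow(x$signal), ncol(x$signal),
              x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Construct a segment
#'
#' @param data Channels x time numeric matrix (microvolts, or differenced
#'   units after [first_difference()]).
#' @param participant_id Integer participant label.
#' @param task Task index 1..15 (14 runs plus the pooled rest signal).
#' @param event Event index 1..3.
#' @return An object of class `segment`.
#' @export
segment <- function(data, participant_id = NA_integer_, task = NA_integer_,
                    event = NA_integer_) {
  data <- as.matrix(data)
  if (length(data) == 0L) stop("segment: data must be non-empty")
  if (!is.na(task) && (task < 1L || task > 15L)) {
    stop("segment: task must lie in 1..15")
  }
  if (!is.na(event) && (event < 1L || event > 3L)) {
    stop("segment: event must lie in 1..3")
  }
  structure(list(data = data, participant_id = as.integer(participant_id),
                 task = as.integer(task), event = as.integer(event)),
            class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment> participant %s, task %s, event %s: %d channels x %d samples\n",
              x$participant_id, x$task, x$event, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Cut a recording into per-event segments
#'
#' Each event row yields the signal slice `[latency, latency + duration - 1]`.
#' With `concatenate_same_event = TRUE` all occurrences of the same code in
#' the run are concatenated in time order, giving at most one segment per
#' event code — the form used for transfer-entropy estimation, since the
#' reference protocol repeats each event several times per run.
#'
#' @param rec A [recording()].
#' @param concatenate_same_event Concatenate occurrences of the same code?
#' @param task Task index recorded on the returned segments (defaults to the
#'   recording's run id).
#' @return A list of [segment()] objects.
#' @export
extract_segments <- function(rec, concatenate_same_event = FALSE,
                             task = rec$run_id) {
  ev <- rec$events
  if (nrow(ev) == 0L) return(list())
  ends <- event_end(ev)
  if (max(ends) > ncol(rec$signal)) {
    stop("extract_segments: event span exceeds signal length")
  }
  slices <- lapply(seq_len(nrow(ev)), function(i) {
    rec$signal[, ev$latency[i]:ends[i], drop = FALSE]
  })
  ev_num <- as.integer(sub("^e", "", ev$code))
  if (!concatenate_same_event) {
    return(lapply(seq_along(slices), function(i) {
      segment(slices[[i]], rec$participant_id, task, ev_num[i])
    }))
  }
  codes <- sort(unique(ev_num))
  lapply(codes, function(e) {
    segment(do.call(cbind, slices[ev_num == e]), rec$participant_id, task, e)
  })
}

#' Pool the rest spans of several runs into one segment
#'
#' The study design carries a fifteenth "task": the rest (e1) signal pooled
#' across the non-baseline runs of a participant. All e1 spans of the given
#' recordings are concatenated in run order.
#'
#' @param recordings List of [recording()] objects from one participant.
#' @return A [segment()] with `task = 15`, `event = 1`.
#' @export
pooled_rest_segment <- function(recordings) {
  pieces <- lapply(recordings, function(rec) {
    segs <- extract_segments(rec, concatenate_same_event = TRUE)
    ev <- vapply(segs, function(s) s$event, integer(1))
    if (!any(ev == 1L)) return(NULL)
    segs[[which(ev == 1L)]]$data
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces)) stop("pooled_rest_segment: no e1 spans found")
  segment(do.call(cbind, pieces), recordings[[1L]]$participant_id,
          task = 15L, event = 1L)
}
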