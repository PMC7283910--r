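#' Event tables
#'
#' An event table segments a run into annotated spans. Each row holds an
#' event code (`e1` rest, `e2` left/both-fists onset, `e3` right-fist/feet
#' onset), a 1-based start sample (`latency`) and a span length in samples
#' (`duration`). Latencies are strictly increasing and spans never overlap.
#'
#' @param code Character vector over `c("e1","e2","e3")`, or integers 1..3.
#' @param latency Integer vector of 1-based start samples.
#' @param duration Integer vector of span lengths (samples), all positive.
#' @return A `data.frame` of class `event_table` with columns
#'   `code`, `latency`, `duration`.
#' @export
#' @examples
#' ev <- event_table(c("e1", "e3"), c(1, 1313), c(672, 656))
#' event_end(ev)          # 672 1968
#' intermission(ev)       # 641
event_table <- function(code = character(), latency = integer(),
                        duration = integer()) {
  if (is.numeric(code)) code <- paste0("e", as.integer(code))
  code <- as.character(code)
  latency <- as.integer(latency)
  duration <- as.integer(duration)
  stopifnot(length(code) == length(latency),
            length(code) == length(duration))
  tab <- data.frame(code = code, latency = latency, duration = duration,
                    stringsAsFactors = FALSE)
  class(tab) <- c("event_table", "data.frame")
  validate_event_table(tab)
}

validate_event_table <- function(tab) {
  if (nrow(tab) == 0L) return(tab)
  if (!all(tab$code %in% c("e1", "e2", "e3"))) {
    stop("event_table: codes restricted to e1/e2/e3; got: ",
         paste(setdiff(unique(tab$code), c("e1", "e2", "e3")), collapse = ", "))
  }
  if (any(tab$duration <= 0L)) stop("event_table: durations must be positive")
  if (any(tab$latency < 1L)) stop("event_table: latencies are 1-based (>= 1)")
  if (is.unsorted(tab$latency, strictly = TRUE)) {
    stop("event_table: latencies must be strictly increasing")
  }
  ends <- tab$latency + tab$duration - 1L
  if (nrow(tab) > 1L && any(tab$latency[-1L] <= ends[-nrow(tab)])) {
    stop("event_table: overlapping events")
  }
  tab
}

#' Last sample of an event span
#'
#' The inclusive end sample of each event: `latency + duration - 1`.
#' An event starting at sample 1 with duration 672 lasts until sample 672.
#'
#' @param events An [event_table()] (or a single-row subset of one).
#' @return Integer vector of end samples.
#' @export
event_end <- function(events) {
  events$latency + events$duration - 1L
}

#' Intermission between consecutive events
#'
#' The gap convention is `next_start - previous_end`, so the Table-2-style
#' alternation (an event ending at 672 followed by one starting at 1313)
#' gives 641. Back-to-back events give 1.
#'
#' @param events An [event_table()] with at least two rows, or the
#'   `previous` event table when `next_events` is supplied.
#' @param next_events Optional second [event_table()]; when given, gaps are
#'   computed between the rows of `events` and `next_events` pairwise.
#' @return Integer vector of gaps (length `nrow - 1` in the single-table form).
#' @export
intermission <- function(events, next_events = NULL) {
  if (is.null(next_events)) {
    if (nrow(events) < 2L) stop("intermission: need at least two events")
    prev <- events[-nrow(events), , drop = FALSE]
    nxt <- events[-1L, , drop = FALSE]
  } else {
    prev <- events
    nxt <- next_events
  }
  ends <- event_end(prev)
  if (any(nxt$latency <= ends)) stop("intermission: overlapping events")
  as.integer(nxt$latency - ends)
}

#' Read or write an event table as TSV
#'
#' Plain-text interchange format with header `code latency duration`.
#'
#' @param path File path.
#' @param events An [event_table()] (for writing).
#' @return `read_event_table()` returns an [event_table()].
#' @export
read_event_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  event_table(tab$code, tab$latency, tab$duration)
}

#' @rdname read_event_table
#' @export
write_event_table <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
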