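#' Read a recording from EDF+ or the neutral text container
#'
#' `read_recording()` accepts either an EDF/EDF+ file (dispatched on the
#' `.edf` extension, see [read_edf()]) or the package's neutral plain-text
#' container: a tab-delimited signal matrix (rows = channels) at
#' `<stem>.tsv`, a `<stem>.meta` sidecar of `key: value` lines carrying the
#' sampling rate and identifiers, and an optional `<stem>.events.tsv` event
#' table. The neutral container exists so synthetic cohorts round-trip
#' through plain text without an EDF writer.
#'
#' @param path Path to an `.edf` file or to the `<stem>.tsv` signal file
#'   (the bare `<stem>` is also accepted).
#' @param code_map Annotation label map, passed to [read_edf()].
#' @param relaxed Accept non-64-channel files.
#' @return A [recording()].
#' @export
read_recording <- function(path, code_map = c(T0 = "e1", T1 = "e2", T2 = "e3"),
                           relaxed = FALSE) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    return(read_edf(path, code_map, relaxed = relaxed))
  }
  stem <- sub("\\.tsv$", "", path)
  sig_path <- paste0(stem, ".tsv")
  meta_path <- paste0(stem, ".meta")
  if (!file.exists(sig_path)) stop("read_recording: no such file: ", sig_path)
  if (!file.exists(meta_path)) stop("read_recording: missing sidecar: ", meta_path)

  meta <- .read_sidecar(meta_path)
  signal <- as.matrix(utils::read.table(sig_path, sep = "\t"))
  dimnames(signal) <- NULL

  ev_path <- paste0(stem, ".events.tsv")
  events <- if (file.exists(ev_path)) read_event_table(ev_path) else event_table()

  n_ch <- nrow(signal)
  if (!relaxed && n_ch != 64L) {
    stop("read_recording: expected 64 channels, found ", n_ch,
         " (use relaxed = TRUE to accept)")
  }
  recording(signal, as.numeric(meta$sampling_rate), events,
            participant_id = as.integer(meta$participant_id %||% NA),
            run_id = as.integer(meta$run_id %||% NA),
            channels = if (n_ch == 64L) channel_map() else NULL)
}

#' Write a recording as the neutral text container
#'
#' @param rec A [recording()].
#' @param stem Output path stem; `<stem>.tsv`, `<stem>.meta` and (when
#'   events are present) `<stem>.events.tsv` are written.
#' @return `stem`, invisibly.
#' @export
write_recording <- function(rec, stem) {
  utils::write.table(rec$signal, paste0(stem, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta <- c(sampling_rate = rec$sampling_rate,
            participant_id = rec$participant_id,
            run_id = rec$run_id)
  writeLines(paste0(names(meta), ": ", unname(meta)), paste0(stem, ".meta"))
  if (nrow(rec$events) > 0L) {
    write_event_table(rec$events, paste0(stem, ".events.tsv"))
  }
  invisible(stem)
}

.read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  out <- lapply(kv, function(m) m[3L])
  names(out) <- vapply(kv, function(m) trimws(m[2L]), character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Write/read a coupling matrix as delimited text
#'
#' The 64x64 transfer-entropy matrix is stored as tab-delimited text with
#' `#`-prefixed header lines naming the (participant, task, event) context
#' and the electrode order.
#'
#' @param m A matrix as returned by [ste_matrix()].
#' @param path File path.
#' @return `read_ste_matrix()` returns the matrix with its context
#'   attributes restored.
#' @export
write_ste_matrix <- function(m, path) {
  ctx <- attr(m, "context")
  hdr <- c(
    sprintf("# participant: %s", ctx$participant_id %||% NA),
    sprintf("# task: %s", ctx$task %||% NA),
    sprintf("# event: %s", ctx$event %||% NA),
    sprintf("# channels: %s", paste(rownames(m) %||% seq_len(nrow(m)),
                                    collapse = " ")))
  writeLines(hdr, path)
  utils::write.table(unclass(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname write_ste_matrix
#' @export
read_ste_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  m <- as.matrix(utils::read.table(text = body, sep = "\t"))
  dimnames(m) <- NULL
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1L]))
  }
  chs <- get_field("channels")
  if (!is.na(chs)) {
    labs <- strsplit(chs, " ")[[1L]]
    if (length(labs) == nrow(m)) rownames(m) <- colnames(m) <- labs
  }
  suppress_na <- function(x) suppressWarnings(as.integer(x))
  attr(m, "context") <- list(participant_id = suppress_na(get_field("participant")),
                             task = suppress_na(get_field("task")),
                             event = suppress_na(get_field("event")))
  class(m) <- c("ste_matrix", class(m))
  m
}
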