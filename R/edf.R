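# Minimal EDF/EDF+ reader: 16-bit sample records plus the "EDF Annotations"
# TAL channel. Covers the layout of the reference motor/imagery recordings.

.edf_field <- function(con, nbytes) {
  trimws(rawToChar(readBin(con, "raw", nbytes)))
}

#' Read an EDF/EDF+ file
#'
#' Parses the fixed-width EDF header, scales the 16-bit samples to physical
#' units, and decodes EDF+ time-stamped annotation lists (TALs) from any
#' "EDF Annotations" signal into an [event_table()]. Annotation onsets are
#' converted to 1-based sample latencies at the ordinary-signal sampling
#' rate; zero-duration annotations are dropped.
#'
#' @param path Path to an `.edf` file.
#' @param code_map Named character vector mapping annotation labels to event
#'   codes; default `c(T0 = "e1", T1 = "e2", T2 = "e3")` as used by the
#'   reference dataset.
#' @param participant_id,run_id Optional labels stored on the result.
#' @param relaxed Allow channel counts other than 64 (montage validation is
#'   then skipped).
#' @return A [recording()].
#' @export
read_edf <- function(path, code_map = c(T0 = "e1", T1 = "e2", T2 = "e3"),
                     participant_id = NA_integer_, run_id = NA_integer_,
                     relaxed = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))

  version <- .edf_field(con, 8L)
  if (!startsWith(version, "0")) stop("read_edf: not an EDF file: ", path)
  invisible(readBin(con, "raw", 80L + 80L + 8L + 8L))  # patient/recording/date/time
  invisible(.edf_field(con, 8L))                       # header byte count
  invisible(.edf_field(con, 44L))                      # reserved ("EDF+C")
  n_records <- as.integer(.edf_field(con, 8L))
  record_dur <- as.numeric(.edf_field(con, 8L))
  ns <- as.integer(.edf_field(con, 4L))

  labels <- vapply(seq_len(ns), function(i) .edf_field(con, 16L), character(1))
  invisible(readBin(con, "raw", 80L * ns))             # transducer
  invisible(readBin(con, "raw", 8L * ns))              # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(.edf_field(con, 8L)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(.edf_field(con, 8L)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(.edf_field(con, 8L)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(.edf_field(con, 8L)), numeric(1))
  invisible(readBin(con, "raw", 80L * ns))             # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(.edf_field(con, 8L)), integer(1))
  invisible(readBin(con, "raw", 32L * ns))             # reserved

  is_annot <- labels == "EDF Annotations"
  sig_idx <- which(!is_annot)
  if (!length(sig_idx)) stop("read_edf: no ordinary signals in ", path)
  fs <- spr[sig_idx[1L]] / record_dur

  chunks <- vector("list", ns)
  for (i in seq_len(ns)) chunks[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw_i <- readBin(con, "raw", 2L * spr[i])
      chunks[[i]][[r]] <- raw_i
    }
  }

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  signal <- matrix(0, nrow = length(sig_idx),
                   ncol = n_records * spr[sig_idx[1L]])
  for (k in seq_along(sig_idx)) {
    i <- sig_idx[k]
    dig <- readBin(do.call(c, chunks[[i]]), "integer", n_records * spr[i],
                   size = 2L, signed = TRUE, endian = "little")
    signal[k, ] <- phys_min[i] + gain[i] * (dig - dig_min[i])
  }

  events <- event_table()
  if (any(is_annot)) {
    tal_raw <- do.call(c, unlist(chunks[is_annot], recursive = FALSE))
    events <- .parse_tals(tal_raw, fs, code_map)
  }

  if (!relaxed && length(sig_idx) != 64L) {
    stop("read_edf: expected 64 channels, found ", length(sig_idx),
         " (use relaxed = TRUE to accept)")
  }
  channels <- if (length(sig_idx) == 64L) channel_map() else NULL
  if (!is.null(channels)) {
    # sanity: header labels must agree with the standard montage where present
    hdr <- toupper(gsub("[. ]+$", "", labels[sig_idx]))
    if (!all(hdr == as.character(channels)) && all(hdr %in% as.character(channels))) {
      channels <- structure(hdr, class = "channel_map")
    }
  }
  recording(signal, fs, events, participant_id, run_id, channels)
}

# Decode EDF+ TALs: "+<onset>(\x15<duration>)?\x14<label>\x14...\x14",
# each TAL terminated by a NUL byte
.parse_tals <- function(raw_bytes, fs, code_map) {
  is_nul <- raw_bytes == as.raw(0L)
  grp <- cumsum(is_nul)
  pieces <- split(raw_bytes[!is_nul], grp[!is_nul])
  tals <- vapply(pieces, rawToChar, character(1))
  code <- character(); latency <- integer(); duration <- integer()
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) next              # timestamp-only TAL
    head <- strsplit(parts[1L], "\x15", fixed = TRUE)[[1L]]
    onset <- suppressWarnings(as.numeric(head[1L]))
    if (is.na(onset)) next
    dur <- if (length(head) >= 2L) as.numeric(head[2L]) else 0
    if (is.na(dur) || dur <= 0) next
    for (lab in parts[-1L]) {
      if (!nzchar(lab)) next
      if (!lab %in% names(code_map)) {
        stop("read_edf: annotation label '", lab,
             "' missing from code_map")
      }
      code <- c(code, unname(code_map[lab]))
      latency <- c(latency, as.integer(round(onset * fs)) + 1L)
      duration <- c(duration, as.integer(round(dur * fs)))
    }
  }
  ord <- order(latency)
  event_table(code[ord], latency[ord], duration[ord])
}
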