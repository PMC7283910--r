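# Minimal EDF+ writer used only to exercise the reader: one data record
# holding the whole signal (16-bit, unit gain) plus a TAL annotation channel.
write_minimal_edf <- function(path, signal, fs, events,
                              labels = as.character(channel_map())) {
  ns <- nrow(signal) + 1L  # + annotation channel
  n <- ncol(signal)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")

  tal_pieces <- list(charToRaw("+0\x14\x14"))
  for (i in seq_len(nrow(events))) {
    onset <- (events$latency[i] - 1L) / fs
    dur <- events$duration[i] / fs
    lab <- c(e1 = "T0", e2 = "T1", e3 = "T2")[[events$code[i]]]
    tal_pieces <- c(tal_pieces,
                    list(charToRaw(sprintf("+%g\x15%g\x14%s\x14",
                                           onset, dur, lab))))
  }
  # each TAL is NUL-terminated
  tal_raw <- do.call(c, lapply(tal_pieces, function(p) c(p, as.raw(0L))))
  annot_samples <- as.integer(ceiling(length(tal_raw) / 2) + 8L)
  tal_raw <- c(tal_raw, raw(2L * annot_samples - length(tal_raw)))

  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(pad("0", 8), pad("X", 80), pad("X", 80),
                   pad("01.01.20", 8), pad("00.00.00", 8),
                   pad(header_bytes, 8), pad("EDF+C", 44),
                   pad(1, 8), pad(n / fs, 8), pad(ns, 4)),
            con, eos = NULL)
  all_labels <- c(labels, "EDF Annotations")
  writeChar(paste0(vapply(all_labels, pad, character(1), w = 16), collapse = ""),
            con, eos = NULL)
  writeChar(strrep(" ", 80L * ns), con, eos = NULL)        # transducer
  writeChar(paste0(rep(pad("uV", 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad(-32768, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad(32767, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad(-32768, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad(32767, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 80L * ns), con, eos = NULL)        # prefiltering
  writeChar(paste0(c(rep(pad(n, 8), ns - 1L), pad(annot_samples, 8)),
                   collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 32L * ns), con, eos = NULL)        # reserved
  for (i in seq_len(nrow(signal))) {
    writeBin(as.integer(round(signal[i, ])), con, size = 2L, endian = "little")
  }
  writeBin(tal_raw, con)
  invisible(path)
}
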