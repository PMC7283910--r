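#' Standard 64-channel montage
#'
#' The electrode montage used throughout the package: the 64 channels of the
#' international 10-10 system retained by the BCI2000 motor/imagery recordings
#' (Nz, F9, F10, FT9, FT10, A1, A2, TP9, TP10, P9 and P10 are excluded).
#' Channel 1 is FC5 and the order matches the numbering of the source records.
#'
#' @return A character vector of 64 electrode labels, class `channel_map`.
#' @export
#' @examples
#' ch <- channel_map()
#' ch[1]            # "FC5"
#' channel_index("CZ", ch)
channel_map <- function() {
  labels <- c(
    "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6",
    "C5",  "C3",  "C1",  "CZ",  "C2",  "C4",  "C6",
    "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6",
    "FP1", "FPZ", "FP2",
    "AF7", "AF3", "AFZ", "AF4", "AF8",
    "F7",  "F5",  "F3",  "F1",  "FZ",  "F2",  "F4",  "F6",  "F8",
    "FT7", "FT8",
    "T7",  "T8",  "T9",  "T10",
    "TP7", "TP8",
    "P7",  "P5",  "P3",  "P1",  "PZ",  "P2",  "P4",  "P6",  "P8",
    "PO7", "PO3", "POZ", "PO4", "PO8",
    "O1",  "OZ",  "O2",  "IZ"
  )
  structure(labels, class = "channel_map")
}

# labels that must never appear in a valid montage
.excluded_electrodes <- c("NZ", "F9", "F10", "FT9", "FT10",
                          "A1", "A2", "TP9", "TP10", "P9", "P10")

#' Look up channel indices by electrode label
#'
#' @param labels Character vector of electrode labels (case-insensitive;
#'   trailing dots as found in raw EDF headers are stripped).
#' @param map A [channel_map()].
#' @return Integer indices into the montage.
#' @export
channel_index <- function(labels, map = channel_map()) {
  clean <- toupper(gsub("[. ]+$", "", labels))
  idx <- match(clean, as.character(map))
  if (anyNA(idx)) {
    stop("channel_map: unknown electrode label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}

#' @export
print.channel_map <- function(x, ...) {
  cat("<channel_map> 64 electrodes (10-10 system), channel 1 =",
      as.character(x)[1], "\n")
  print(as.character(x))
  invisible(x)
}

validate_channel_map <- function(map) {
  labs <- toupper(as.character(map))
  if (length(labs) != 64L) stop("channel_map: expected 64 electrodes")
  if (anyDuplicated(labs)) stop("channel_map: duplicate electrode labels")
  bad <- intersect(labs, .excluded_electrodes)
  if (length(bad)) {
    stop("channel_map: excluded electrodes present: ",
         paste(bad, collapse = ", "))
  }
  invisible(map)
}
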