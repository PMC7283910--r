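#' Band-pass filter specification
#'
#' Defaults follow common EEG practice for the reference dataset: 1--70 Hz
#' pass band with a 60 Hz mains notch. With `fir_order = "auto"` the tap
#' count follows the usual EEG rule of thumb, about 3.3 divided by the
#' normalized transition width, where the transition width is
#' `min(max(band_low / 4, 2), band_low)` Hz; at 160 samples/s with a 1 Hz
#' lower edge this yields 528 taps.
#'
#' @param band_low,band_high Pass-band edges in Hz.
#' @param notch Mains notch frequency in Hz, or `NULL` for none.
#' @param notch_width Total stop-band width of the notch in Hz.
#' @param fir_order `"auto"` or an even tap count.
#' @return A `filter_spec` list.
#' @export
#' @examples
#' spec <- filter_spec()
#' fir_auto_order(spec, 160)   # 528
filter_spec <- function(band_low = 1, band_high = 70, notch = 60,
                        notch_width = 2, fir_order = "auto") {
  if (band_low <= 0 || band_high <= band_low) {
    stop("filter_spec: need 0 < band_low < band_high")
  }
  if (!is.null(notch) && (notch <= band_low || notch >= band_high)) {
    stop("filter_spec: notch must lie inside the pass band")
  }
  structure(list(band_low = band_low, band_high = band_high, notch = notch,
                 notch_width = notch_width, fir_order = fir_order),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @param spec A `filter_spec`.
#' @param sampling_rate Samples per second.
#' @export
fir_auto_order <- function(spec, sampling_rate) {
  if (!identical(spec$fir_order, "auto")) return(as.integer(spec$fir_order))
  if (spec$band_high >= sampling_rate / 2) {
    stop("filter_spec: band_high must be below the Nyquist frequency")
  }
  tbw <- min(max(spec$band_low / 4, 2), spec$band_low)  # Hz
  n <- ceiling(3.3 / (tbw / sampling_rate))
  as.integer(n + n %% 2L)  # even order -> odd, symmetric tap count
}

# standard linear convolution (polynomial product)
.conv <- function(a, b) stats::convolve(a, rev(b), type = "open")

# zero-phase filtering of all channels at once: the forward-backward pass
# of each symmetric FIR is one convolution with its self-convolution, so
# the whole cascade collapses into a single combined kernel applied by FFT
# after reflect-padding each channel by one filter length
.fir_filtfilt_matrix <- function(sig, kernels) {
  g <- Reduce(function(acc, h) .conv(acc, .conv(h, h)), kernels[-1L],
              .conv(kernels[[1L]], kernels[[1L]]))
  delay <- (length(g) - 1L) %/% 2L
  n <- ncol(sig)
  pad <- min(max(vapply(kernels, length, integer(1))), n - 1L)
  np <- n + 2L * pad
  N <- stats::nextn(np + length(g) - 1L, 2L)
  X <- matrix(0, N, nrow(sig))
  for (i in seq_len(nrow(sig))) {
    x <- sig[i, ]
    X[seq_len(np), i] <- c(rev(x[2L:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  }
  G <- stats::fft(c(g, numeric(N - length(g))))
  Y <- Re(stats::mvfft(stats::mvfft(X) * G, inverse = TRUE)) / N
  t(Y[(delay + pad + 1L):(delay + pad + n), , drop = FALSE])
}

#' Zero-phase FIR band-pass (and notch) filter
#'
#' Applies a windowed-sinc (Hamming) FIR band-pass, then a FIR band-stop
#' notch when requested, each as a zero-phase forward-backward pass with
#' reflect padding. Works channel-wise on a [recording()], a [segment()] or
#' a bare channels-by-time matrix; shape is preserved.
#'
#' @param x A [recording()], [segment()] or numeric matrix.
#' @param spec A [filter_spec()].
#' @param sampling_rate Required when `x` is a segment or matrix.
#' @return An object of the same class as `x`.
#' @export
bandpass <- function(x, spec = filter_spec(), sampling_rate = NULL) {
  UseMethod("bandpass")
}

#' @export
bandpass.recording <- function(x, spec = filter_spec(), sampling_rate = NULL) {
  x$signal <- .bandpass_matrix(x$signal, spec, x$sampling_rate)
  x
}

#' @export
bandpass.segment <- function(x, spec = filter_spec(), sampling_rate = NULL) {
  if (is.null(sampling_rate)) stop("bandpass: sampling_rate required for segments")
  x$data <- .bandpass_matrix(x$data, spec, sampling_rate)
  x
}

#' @export
bandpass.matrix <- function(x, spec = filter_spec(), sampling_rate = NULL) {
  if (is.null(sampling_rate)) stop("bandpass: sampling_rate required for matrices")
  .bandpass_matrix(x, spec, sampling_rate)
}

.bandpass_matrix <- function(sig, spec, fs) {
  ord <- fir_auto_order(spec, fs)
  if (ncol(sig) <= 3L * ord) {
    stop("bandpass: signal length ", ncol(sig),
         " too short for filter order ", ord)
  }
  nyq <- fs / 2
  kernels <- list(as.numeric(signal::fir1(ord, c(spec$band_low, spec$band_high) / nyq,
                                          type = "pass")))
  if (!is.null(spec$notch)) {
    half <- spec$notch_width / 2
    kernels <- c(kernels,
                 list(as.numeric(signal::fir1(ord, c(spec$notch - half, spec$notch + half) / nyq,
                                              type = "stop"))))
  }
  .fir_filtfilt_matrix(sig, kernels)
}

#' Artifact-removal hook
#'
#' Artifact handling (e.g. ICA-based ocular/EMG cleaning) is delegated to a
#' user-supplied function mapping the channels-by-time signal matrix to a
#' cleaned matrix of identical shape; the default hook is the identity, and
#' the synthetic cohort generator produces artifact-free signals so the
#' identity hook is sufficient for simulated data.
#'
#' @param rec A [recording()].
#' @param hook Function `matrix -> matrix`; must preserve dimensions.
#' @return The cleaned [recording()].
#' @export
artifact_removal <- function(rec, hook = identity) {
  cleaned <- tryCatch(hook(rec$signal), error = function(e) {
    stop("artifact_removal: hook failed: ", conditionMessage(e))
  })
  if (!identical(dim(cleaned), dim(rec$signal))) {
    stop("artifact_removal: hook changed the signal shape")
  }
  rec$signal <- cleaned
  rec
}

#' First-order difference of a segment
#'
#' Replaces each channel by its lag-1 difference, `out[n] = in[n+1] - in[n]`,
#' shortening the time axis by one sample. Differencing removes slow trends
#' and centres the amplitude distribution before tercile symbolization.
#'
#' @param seg A [segment()] (or matrix).
#' @return A [segment()] (or matrix) with one fewer time sample.
#' @export
first_difference <- function(seg) {
  dat <- if (inherits(seg, "segment")) seg$data else as.matrix(seg)
  if (ncol(dat) < 2L) stop("first_difference: need at least 2 time samples")
  d <- dat[, -1L, drop = FALSE] - dat[, -ncol(dat), drop = FALSE]
  if (inherits(seg, "segment")) {
    seg$data <- d
    attr(seg, "differenced") <- TRUE
    seg
  } else {
    d
  }
}
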