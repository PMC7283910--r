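#' Complex eigen-spectrum of a coupling matrix
#'
#' All eigenvalues (with multiplicity) of the asymmetric transfer-entropy
#' matrix, in a canonical order that removes the eigen-solver's arbitrary
#' ordering: descending modulus, then descending real part, then
#' non-negative imaginary part first. For a real input matrix the spectrum
#' is closed under complex conjugation.
#'
#' @param m Square numeric matrix (an [ste_matrix()] or plain matrix).
#' @return An `eigen_spectrum`: list with `values` (complex vector),
#'   `normalized` flag and the coupling `context`.
#' @export
eigen_spectrum <- function(m) {
  w <- unclass(m)
  if (any(!is.finite(w))) stop("eigen_spectrum: non-finite matrix entries")
  if (nrow(w) != ncol(w)) stop("eigen_spectrum: matrix must be square")
  ev <- eigen(w, only.values = TRUE)$values
  ev <- as.complex(ev)
  ord <- order(-Mod(ev), -Re(ev), Im(ev) < 0)
  structure(list(values = ev[ord], normalized = FALSE,
                 context = attr(m, "context")),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("<eigen_spectrum> %d eigenvalues%s, |lambda| in [%.4g, %.4g]\n",
              length(x$values), if (x$normalized) " (z-scored)" else "",
              min(Mod(x$values)), max(Mod(x$values))))
  invisible(x)
}

#' Z-score normalize a spectrum
#'
#' Standardizes the real and imaginary parts independently, each to mean 0
#' and sample standard deviation 1, within the matrix. A zero-variance
#' component cannot be standardized; it is set to 0 with a warning.
#'
#' @param spectrum An [eigen_spectrum()].
#' @return The normalized `eigen_spectrum`.
#' @export
zscore_spectrum <- function(spectrum) {
  std <- function(v, what) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("zscore_spectrum: zero-variance ", what,
              " component left at 0")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  re <- std(Re(spectrum$values), "real")
  im <- std(Im(spectrum$values), "imaginary")
  spectrum$values <- complex(real = re, imaginary = im)
  spectrum$normalized <- TRUE
  spectrum
}

#' Canonical spectrum vector
#'
#' The fixed-length fingerprint vector used in the cohort-level ANOVA
#' layout: the normalized real parts of all eigenvalues in canonical order,
#' followed by the normalized imaginary parts (length 128 for a 64-channel
#' matrix).
#'
#' @param spectrum An [eigen_spectrum()], z-scored first if not already.
#' @return Numeric vector of length `2 * n_eigenvalues`.
#' @export
spectrum_vector <- function(spectrum) {
  if (!spectrum$normalized) spectrum <- zscore_spectrum(spectrum)
  c(Re(spectrum$values), Im(spectrum$values))
}

#' Coarse-grain complex eigenvalues onto a 2-D grid
#'
#' Bins each eigenvalue into square cells of side `theta`: cell
#' `(ceiling((Re - re_min)/theta), ceiling((Im - im_min)/theta))`, with the
#' lower edge of the first cell closed. When explicit shared `ranges` are
#' given every point must fall inside them unless `clip = TRUE`, in which
#' case out-of-range points are counted into the boundary cells and their
#' number is recorded in the `clipped` attribute.
#'
#' @param points Complex vector (or an [eigen_spectrum()]).
#' @param theta Cell size on the eigenvalue scale.
#' @param ranges Optional list with `re = c(min, max)`, `im = c(min, max)`
#'   shared across grids; default is the range of `points`.
#' @param clip Clip out-of-range points to the boundary cells?
#' @return A `spectrum_grid`: list with integer `counts` (rows = real axis
#'   cells), `theta`, `re_range`, `im_range`.
#' @export
coarse_grain <- function(points, theta = 1, ranges = NULL, clip = FALSE) {
  if (inherits(points, "eigen_spectrum")) points <- points$values
  if (theta <= 0) stop("coarse_grain: theta must be positive")
  re <- Re(points); im <- Im(points)
  if (is.null(ranges)) {
    ranges <- list(re = range(re), im = range(im))
  }
  n_clip <- sum(re < ranges$re[1L] | re > ranges$re[2L] |
                im < ranges$im[1L] | im > ranges$im[2L])
  if (n_clip > 0L && !clip) {
    stop("coarse_grain: ", n_clip, " point(s) outside the explicit ranges")
  }
  ncell <- function(rng) max(1L, as.integer(ceiling((rng[2L] - rng[1L]) / theta)))
  nr <- ncell(ranges$re); ni <- ncell(ranges$im)
  cell <- function(v, rng, k) {
    i <- as.integer(ceiling((v - rng[1L]) / theta))
    pmin(pmax(i, 1L), k)  # lower edge of first cell closed; clip to bounds
  }
  ir <- cell(re, ranges$re, nr)
  ii <- cell(im, ranges$im, ni)
  counts <- matrix(0L, nr, ni)
  for (p in seq_along(ir)) counts[ir[p], ii[p]] <- counts[ir[p], ii[p]] + 1L
  structure(list(counts = counts, theta = theta,
                 re_range = ranges$re, im_range = ranges$im,
                 clipped = n_clip),
            class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf("<spectrum_grid> %dx%d cells (theta = %g), %d points%s\n",
              nrow(x$counts), ncol(x$counts), x$theta, sum(x$counts),
              if (x$clipped > 0L) sprintf(" (%d clipped)", x$clipped) else ""))
  invisible(x)
}

grids_aligned <- function(a, b) {
  isTRUE(all.equal(a$theta, b$theta)) &&
    isTRUE(all.equal(a$re_range, b$re_range)) &&
    isTRUE(all.equal(a$im_range, b$im_range)) &&
    identical(dim(a$counts), dim(b$counts))
}

#' Write/read a spectrum grid as delimited text
#'
#' @param grid A [coarse_grain()] result.
#' @param path File path.
#' @export
write_spectrum_grid <- function(grid, path) {
  hdr <- c(sprintf("# theta: %.17g", grid$theta),
           sprintf("# re_range: %.17g %.17g", grid$re_range[1L], grid$re_range[2L]),
           sprintf("# im_range: %.17g %.17g", grid$im_range[1L], grid$im_range[2L]))
  writeLines(hdr, path)
  utils::write.table(grid$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname write_spectrum_grid
#' @export
read_spectrum_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  num <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)[1L]
    as.numeric(strsplit(trimws(sub(".*?:", "", ln)), " +")[[1L]])
  }
  counts <- as.matrix(utils::read.table(text = body, sep = "\t"))
  dimnames(counts) <- NULL
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, theta = num("theta"),
                 re_range = num("re_range"), im_range = num("im_range"),
                 clipped = 0L),
            class = "spectrum_grid")
}
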