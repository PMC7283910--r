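#' Fit a spectrum-distribution reference set (SDSS)
#'
#' The fitting step of spectrum-distribution set scoring: every participant
#' contributes the eigen-spectra of the three reference-task events; each
#' spectrum is z-score normalized, coarse-grained on a grid shared by the
#' whole cohort (cell size `theta`, ranges pooled over all contributing
#' eigenvalues), and the three event grids are summed cell-wise into the
#' participant's reference fingerprint.
#'
#' @param spectra Named list, one element per participant, each itself a
#'   list of three [eigen_spectrum()] objects (events 1..3 of the reference
#'   task).
#' @param theta Coarse-graining cell size. The default 0.5 is on the
#'   z-scored scale, where the spectrum spans roughly six standard
#'   deviations: half-unit cells give a grid fine enough to separate
#'   individual fingerprints while keeping several eigenvalues per
#'   occupied cell. A cell size of 1 is the natural choice when gridding
#'   raw (unnormalized) eigenvalues whose spread is an order of magnitude
#'   larger.
#' @param normalize Z-score each spectrum before binning (the default;
#'   turning this off grids raw eigenvalues).
#' @return An object of class `sdss_ref` with elements `participants`,
#'   `grids` (one [coarse_grain()] grid each), `theta`, `ranges` and
#'   `normalize`.
#' @seealso [predict.sdss_ref()] for identification, [cross_test()] for the
#'   repeated group protocol.
#' @export
sdss_reference <- function(spectra, theta = 0.5, normalize = TRUE) {
  if (!length(spectra)) stop("sdss_reference: empty cohort")
  ids <- names(spectra)
  if (is.null(ids)) ids <- as.character(seq_along(spectra))
  prep <- lapply(seq_along(spectra), function(k) {
    evs <- spectra[[k]]
    if (length(evs) != 3L) {
      stop("sdss_reference: participant ", ids[k],
           " must contribute all three reference events, got ", length(evs))
    }
    lapply(seq_along(evs), function(e) {
      sp <- evs[[e]]
      if (!inherits(sp, "eigen_spectrum")) {
        stop("sdss_reference: participant ", ids[k], ", event ", e,
             ": not an eigen_spectrum")
      }
      if (normalize && !sp$normalized) sp <- zscore_spectrum(sp)
      sp$values
    })
  })
  pooled <- unlist(prep, recursive = TRUE)
  ranges <- list(re = range(Re(pooled)), im = range(Im(pooled)))
  grids <- lapply(prep, function(evs) {
    gs <- lapply(evs, coarse_grain, theta = theta, ranges = ranges)
    g <- gs[[1L]]
    g$counts <- gs[[1L]]$counts + gs[[2L]]$counts + gs[[3L]]$counts
    g
  })
  names(grids) <- ids
  structure(list(participants = ids, grids = grids, theta = theta,
                 ranges = ranges, normalize = normalize),
            class = "sdss_ref")
}

#' @export
print.sdss_ref <- function(x, ...) {
  cat(sprintf("<sdss_ref> %d participants, %dx%d grid (theta = %g), %d eigenvalues each\n",
              length(x$participants), nrow(x$grids[[1L]]$counts),
              ncol(x$grids[[1L]]$counts), x$theta, sum(x$grids[[1L]]$counts)))
  invisible(x)
}

#' @export
summary.sdss_ref <- function(object, ...) {
  masses <- vapply(object$grids, function(g) sum(g$counts), numeric(1))
  cells <- vapply(object$grids, function(g) sum(g$counts > 0L), numeric(1))
  out <- data.frame(participant = object$participants, mass = masses,
                    occupied_cells = cells, row.names = NULL)
  cat(sprintf("SDSS reference set: %d participants, theta = %g, real range [%.3g, %.3g], imaginary range [%.3g, %.3g]\n",
              length(object$participants), object$theta,
              object$ranges$re[1L], object$ranges$re[2L],
              object$ranges$im[1L], object$ranges$im[2L]))
  print(out)
  invisible(out)
}

#' Histogram-intersection overlap between two aligned grids
#'
#' The SDSS score: the sum over cells of the minimum of the two counts.
#' It is symmetric, bounded by the smaller total mass, and equals the
#' total mass exactly when the grids coincide.
#'
#' @param test,reference Cell-aligned [coarse_grain()] grids.
#' @return Non-negative overlap score.
#' @export
overlap_score <- function(test, reference) {
  if (!grids_aligned(test, reference)) {
    stop("overlap_score: grids are not cell-aligned (theta/ranges differ)")
  }
  sum(pmin(test$counts, reference$counts))
}

#' Identify a participant from a test spectrum
#'
#' Scores a held-out spectrum against every reference fingerprint by
#' histogram intersection and labels it with the highest-scoring
#' participant. Test eigenvalues outside the reference ranges are clipped
#' into the boundary cells (their number is reported). Ties are broken
#' toward the lowest participant id and flagged.
#'
#' @param object An [sdss_reference()] fit.
#' @param newdata An [eigen_spectrum()], a pre-aligned `spectrum_grid`, or
#'   a list of either (one result per element).
#' @param ... Unused.
#' @return An `sdss_scores` object: `scores` (named numeric), `winner`
#'   (participant id), `tie` flag and `clipped` count — or a list of such
#'   objects when `newdata` is a list.
#' @export
predict.sdss_ref <- function(object, newdata, ...) {
  if (is.list(newdata) && !inherits(newdata, c("eigen_spectrum", "spectrum_grid"))) {
    return(lapply(newdata, function(x) predict(object, x)))
  }
  grid <- if (inherits(newdata, "spectrum_grid")) {
    newdata
  } else {
    sp <- newdata
    if (object$normalize && !sp$normalized) sp <- zscore_spectrum(sp)
    coarse_grain(sp$values, theta = object$theta, ranges = object$ranges,
                 clip = TRUE)
  }
  scores <- vapply(object$grids, overlap_score, numeric(1), test = grid)
  top <- which(scores == max(scores))
  structure(list(scores = scores,
                 winner = object$participants[top[1L]],
                 tie = length(top) > 1L,
                 clipped = grid$clipped),
            class = "sdss_scores")
}

#' @export
print.sdss_scores <- function(x, ...) {
  cat(sprintf("<sdss_scores> winner: participant %s (score %g%s)%s\n",
              x$winner, max(x$scores), if (x$tie) ", tie" else "",
              if (x$clipped > 0L) sprintf("; %d eigenvalue(s) clipped", x$clipped) else ""))
  invisible(x)
}

#' @export
plot.sdss_scores <- function(x, ...) {
  graphics::barplot(x$scores, names.arg = names(x$scores),
                    xlab = "participant", ylab = "overlap score",
                    main = paste("SDSS scores - winner:", x$winner), ...)
  invisible(x)
}

#' @export
plot.sdss_ref <- function(x, participant = x$participants[1L], ...) {
  g <- x$grids[[as.character(participant)]]
  graphics::image(seq_len(nrow(g$counts)), seq_len(ncol(g$counts)), g$counts,
                  xlab = "real-part cell", ylab = "imaginary-part cell",
                  main = paste("Reference fingerprint, participant", participant),
                  ...)
  invisible(x)
}

#' Repeated cross-test identification protocol
#'
#' The cohort-level evaluation: three groups of held-out task spectra (one
#' spectrum per participant per group) are given; each draw partitions the
#' participants into three disjoint subsets as equal in size as possible,
#' assigns subset `g` to test group `g`, identifies every resulting test
#' item against the reference set, and records the fraction of correct
#' labels over the whole cohort. With 99 participants this is the classic
#' 3 x 33 split. Identification outcomes per (group, participant) are
#' deterministic, so they are computed once and the draws only resample the
#' partition.
#'
#' @param object An [sdss_reference()] fit.
#' @param groups List of three named lists; `groups[[g]][[id]]` is the
#'   held-out [eigen_spectrum()] (or aligned grid) of participant `id` in
#'   test group `g`. Every group must cover all reference participants.
#' @param n_draws Number of random group draws.
#' @param seed Seed for the draw sampler.
#' @return A `cross_test` object: per-draw `accuracies`, `mean_accuracy`,
#'   `n_draws`, `group_sizes` and the per-(group, participant) `correct`
#'   matrix.
#' @export
cross_test <- function(object, groups, n_draws = 1000L, seed = NULL) {
  if (length(groups) != 3L) stop("cross_test: exactly three test groups required")
  ids <- object$participants
  n <- length(ids)
  for (g in 1:3) {
    missing <- setdiff(ids, names(groups[[g]]))
    if (length(missing)) {
      stop("cross_test: group ", g, " missing participant(s): ",
           paste(missing, collapse = ", "))
    }
  }
  sizes <- rep(n %/% 3L, 3L) + c(rep(1L, n %% 3L), rep(0L, 3L - n %% 3L))
  correct <- matrix(FALSE, nrow = 3L, ncol = n, dimnames = list(NULL, ids))
  for (g in 1:3) {
    for (id in ids) {
      pred <- predict(object, groups[[g]][[id]])
      correct[g, id] <- identical(pred$winner, id)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  accuracies <- vapply(seq_len(n_draws), function(d) {
    perm <- sample.int(n)
    grp <- rep.int(1:3, times = sizes)
    sum(correct[cbind(grp, perm)]) / n
  }, numeric(1))
  structure(list(accuracies = accuracies,
                 mean_accuracy = mean(accuracies),
                 n_draws = n_draws, group_sizes = sizes, correct = correct),
            class = "cross_test")
}

#' @export
print.cross_test <- function(x, ...) {
  cat(sprintf("<cross_test> %d draws, group sizes %s: mean accuracy %.4f (range %.4f-%.4f)\n",
              x$n_draws, paste(x$group_sizes, collapse = "/"),
              x$mean_accuracy, min(x$accuracies), max(x$accuracies)))
  invisible(x)
}
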