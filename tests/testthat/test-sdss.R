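# small synthetic spectra with controllable separation: participant k's
# eigenvalues cluster around a participant-specific centre
toy_spectrum <- function(centre, n = 64, seed = 1, spread = 0.3) {
  set.seed(seed)
  vals <- complex(real = centre[1] + rnorm(n, sd = spread),
                  imaginary = centre[2] + rnorm(n, sd = spread))
  structure(list(values = vals, normalized = TRUE, context = NULL),
            class = "eigen_spectrum")
}

toy_cohort_spectra <- function(n_participants, spread = 0.3, seed0 = 100) {
  centres <- cbind(cos(2 * pi * seq_len(n_participants) / n_participants),
                   sin(2 * pi * seq_len(n_participants) / n_participants)) * 3
  out <- lapply(seq_len(n_participants), function(p) {
    lapply(1:3, function(e) {
      toy_spectrum(centres[p, ], seed = seed0 + 10 * p + e, spread = spread)
    })
  })
  names(out) <- as.character(seq_len(n_participants))
  out
}

test_that("reference fitting sums the three event grids on shared ranges", {
  sp <- toy_spectrum(c(0, 0), seed = 2)
  ref <- sdss_reference(list(`1` = list(sp, sp, sp)), normalize = FALSE)
  single <- coarse_grain(sp$values, theta = ref$theta,
                         ranges = ref$ranges)
  expect_identical(ref$grids[["1"]]$counts, 3L * single$counts)
  expect_identical(sum(ref$grids[["1"]]$counts), 192L)  # 3 x 64 eigenvalues

  # disjoint cohorts have disjoint grid support
  spA <- toy_spectrum(c(-3, 0), seed = 3)
  spB <- toy_spectrum(c(3, 0), seed = 4)
  ref2 <- sdss_reference(list(A = list(spA, spA, spA),
                              B = list(spB, spB, spB)), normalize = FALSE)
  expect_identical(sum(ref2$grids$A$counts * ref2$grids$B$counts), 0L)

  expect_error(sdss_reference(list(`1` = list(sp, sp))), "three")
  expect_error(sdss_reference(list()), "empty")
})

test_that("overlap score is the histogram intersection", {
  sp <- toy_spectrum(c(0, 0), seed = 5)
  g <- coarse_grain(sp$values, theta = 0.5)
  expect_identical(overlap_score(g, g), sum(g$counts))

  mk <- function(counts) {
    structure(list(counts = counts, theta = 1, re_range = c(0, 2),
                   im_range = c(0, 1), clipped = 0L),
              class = "spectrum_grid")
  }
  a <- mk(matrix(c(2L, 0L), 2, 1))
  b <- mk(matrix(c(1L, 5L), 2, 1))
  expect_identical(overlap_score(a, b), 1L)
  expect_identical(overlap_score(mk(matrix(c(3L, 0L), 2, 1)),
                                 mk(matrix(c(0L, 4L), 2, 1))), 0L)

  # symmetry and the min-mass bound
  expect_identical(overlap_score(a, b), overlap_score(b, a))
  expect_lte(overlap_score(a, b), min(sum(a$counts), sum(b$counts)))

  misaligned <- mk(matrix(c(1L, 1L), 2, 1))
  misaligned$theta <- 2
  expect_error(overlap_score(a, misaligned), "aligned")
})

test_that("identification recovers the generating participant", {
  spectra <- toy_cohort_spectra(6)
  ref <- sdss_reference(spectra, normalize = FALSE)

  # self-identification: a reference event spectrum scores its own label
  pred <- predict(ref, spectra[["3"]][[1]])
  expect_identical(pred$winner, "3")
  expect_false(pred$tie)

  # held-out draws from the same centres are recovered
  correct <- 0
  for (p in 1:6) {
    test_sp <- toy_spectrum(c(cos(2 * pi * p / 6), sin(2 * pi * p / 6)) * 3,
                            seed = 999 + p)
    pr <- predict(ref, test_sp)
    correct <- correct + (pr$winner == as.character(p))
  }
  expect_gte(correct, 5)

  # out-of-range eigenvalues are clipped and counted
  far <- toy_spectrum(c(30, 30), seed = 7)
  pr_far <- predict(ref, far)
  expect_gt(pr_far$clipped, 0)

  # an all-zero test grid ties every participant at score 0
  empty <- structure(list(counts = 0L * ref$grids[[1]]$counts,
                          theta = ref$grids[[1]]$theta,
                          re_range = ref$grids[[1]]$re_range,
                          im_range = ref$grids[[1]]$im_range, clipped = 0L),
                     class = "spectrum_grid")
  pr0 <- predict(ref, empty)
  expect_true(all(pr0$scores == 0))
  expect_true(pr0$tie)
  expect_identical(pr0$winner, ref$participants[1])
})

test_that("cross test partitions exhaustively and is seed-deterministic", {
  spectra <- toy_cohort_spectra(6, spread = 0.2)
  ref <- sdss_reference(spectra, normalize = FALSE)
  groups <- lapply(1:3, function(g) {
    out <- lapply(1:6, function(p) {
      toy_spectrum(c(cos(2 * pi * p / 6), sin(2 * pi * p / 6)) * 3,
                   seed = 5000 + 100 * g + p, spread = 0.2)
    })
    names(out) <- as.character(1:6)
    out
  })
  ct1 <- cross_test(ref, groups, n_draws = 50, seed = 31)
  ct2 <- cross_test(ref, groups, n_draws = 50, seed = 31)
  expect_identical(ct1$accuracies, ct2$accuracies)
  expect_identical(ct1$group_sizes, c(2L, 2L, 2L))
  expect_true(all(ct1$accuracies >= 0 & ct1$accuracies <= 1))
  expect_equal(ct1$mean_accuracy, mean(ct1$accuracies))
  # well-separated cohort: every draw perfect
  expect_true(all(ct1$accuracies == 1))

  expect_error(cross_test(ref, groups[1:2]), "three")
  expect_error(cross_test(ref, list(groups[[1]][1:3], groups[[2]],
                                    groups[[3]])), "missing")
})

test_that("indistinguishable references yield exact chance-level accuracy", {
  # identical grids for everyone: ties always resolve to participant 1,
  # so each draw scores exactly 1/N
  sp <- toy_spectrum(c(0, 0), seed = 8)
  spectra <- lapply(1:5, function(p) list(sp, sp, sp))
  names(spectra) <- as.character(1:5)
  ref <- sdss_reference(spectra, normalize = FALSE)
  groups <- lapply(1:3, function(g) {
    out <- lapply(1:5, function(p) sp)
    names(out) <- as.character(1:5)
    out
  })
  ct <- cross_test(ref, groups, n_draws = 100, seed = 9)
  expect_true(all(ct$accuracies == 1 / 5))
  expect_equal(ct$mean_accuracy, 0.2)
})
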