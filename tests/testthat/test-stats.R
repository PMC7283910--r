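test_that("Frobenius distance closed forms and triangle inequality", {
  set.seed(1)
  a <- random_ste_like(64)
  expect_equal(matrix_distance(a, a), 0)
  expect_equal(matrix_distance(a, a + 1), 64)  # sqrt(64*64*1)
  for (k in 1:10) {
    x <- random_ste_like(8); y <- random_ste_like(8); z <- random_ste_like(8)
    expect_lte(matrix_distance(x, z),
               matrix_distance(x, y) + matrix_distance(y, z) + 1e-12)
  }
  expect_error(matrix_distance(a, a[1:3, 1:3]), "shape")
})

test_that("pair counts reproduce the cohort combinatorics", {
  expect_equal(pair_count(99), 4851)
  expect_equal(pair_count(45), 990)   # 15 tasks x 3 events
  expect_equal(pair_count(2), 1)
  expect_error(pair_count(1), "n >= 2")
})

test_that("distance summaries: degenerate cohort and group bookkeeping", {
  mk <- function(p, t, e, fill) {
    m <- matrix(fill, 4, 4)
    attr(m, "context") <- list(participant_id = p, task = t, event = e)
    m
  }
  # identical matrices everywhere -> both means 0
  mats <- list()
  for (p in 1:3) for (t in 1:2) for (e in 1:2) {
    mats[[length(mats) + 1]] <- mk(p, t, e, 1)
  }
  ds <- distance_summaries(mats)
  expect_equal(ds$between$mean, 0)
  expect_equal(ds$within$mean, 0)
  expect_identical(ds$between$n_pairs, as.integer(pair_count(3)))
  expect_identical(ds$within$n_pairs, as.integer(pair_count(4)))

  # participant-specific fill, constant across conditions: between > within = 0
  mats2 <- list()
  for (p in 1:3) for (t in 1:2) for (e in 1:2) {
    mats2[[length(mats2) + 1]] <- mk(p, t, e, p)
  }
  ds2 <- distance_summaries(mats2)
  expect_gt(ds2$between$mean, 0)
  expect_equal(ds2$within$mean, 0)

  expect_error(distance_summaries(mats[1:4]), "2 participants")
})

test_that("two-sample z-test closed form and normal critical values", {
  zt <- two_sample_ztest(5, 1, 100, 4, 1, 100)
  expect_equal(zt$z, 7.071, tolerance = 1e-4)       # 1 / sqrt(0.02)
  expect_equal(round(zt$crit_one_tailed, 3), 2.326)
  expect_equal(round(zt$crit_two_tailed, 3), 2.576)
  expect_lt(zt$p_two_tailed, 1e-10)

  expect_equal(two_sample_ztest(3, 2, 50, 3, 2, 50)$z, 0)
  expect_error(two_sample_ztest(1, 0, 10, 2, 1, 10), "variance")

  # agrees with the pooled formula on symmetric inputs
  zt2 <- two_sample_ztest(10, 2, 30, 8, 2, 30)
  pooled <- (10 - 8) / (2 * sqrt(2 / 30))
  expect_equal(zt2$z, pooled)
})

test_that("two-way ANOVA decomposes sums of squares additively", {
  set.seed(2)
  # 4 row levels x 3 replicates x 5 columns
  data <- matrix(rnorm(12 * 5), 12, 5)
  tab <- two_way_anova(data, n_row_levels = 4)
  ss <- tab$SS
  expect_equal(ss[5], sum(ss[1:4]), tolerance = 1e-10)
  expect_identical(tab$df, c(4L, 3L, 12L, 40L, 59L))
  expect_equal(tab$df[5], sum(tab$df[1:4]))

  # all-equal data: every SS is zero
  tab0 <- two_way_anova(matrix(7, 12, 5), n_row_levels = 4)
  expect_equal(tab0$SS, rep(0, 5))

  expect_error(two_way_anova(matrix(0, 10, 3), n_row_levels = 4),
               "n_replicates")
})

test_that("ANOVA matches stats::aov on a small balanced layout", {
  set.seed(3)
  r <- 3L; reps <- 4L; cc <- 5L
  data <- matrix(rnorm(r * reps * cc, sd = 2), r * reps, cc)
  tab <- two_way_anova(data, n_row_levels = r)

  long <- data.frame(
    y = as.vector(data),
    col = factor(rep(seq_len(cc), each = r * reps)),
    row = factor(rep(rep(seq_len(r), each = reps), times = cc)))
  fit <- summary(stats::aov(y ~ col * row, data = long))[[1]]
  # aov rows are: col, row, col:row, Residuals
  expect_equal(tab$SS[1:4], fit[["Sum Sq"]], tolerance = 1e-8)
  expect_equal(tab$df[1:4], fit[["Df"]])
  expect_equal(tab$F[1:3], fit[["F value"]][1:3], tolerance = 1e-8)
  expect_equal(tab$p[1:3], fit[["Pr(>F)"]][1:3], tolerance = 1e-8)
})

test_that("a pure column effect loads on the column factor only", {
  set.seed(4)
  r <- 5L; reps <- 10L; cc <- 6L
  effect <- rep(seq_len(cc) * 2, each = r * reps)
  data <- matrix(rnorm(r * reps * cc) + effect, r * reps, cc)
  tab <- two_way_anova(data, n_row_levels = r)
  expect_gt(tab$F[1], 50)
  expect_lt(tab$F[2], 3)
  expect_lt(tab$F[3], 3)
  expect_lt(tab$p[1], 1e-6)
})

test_that("the cohort spectrum layout yields the documented dfs", {
  set.seed(5)
  # 45 task-event conditions x 128 spectrum components per 99 participants
  data <- matrix(rnorm(5760 * 99), 5760, 99)
  tab <- two_way_anova(data, n_row_levels = 45)
  expect_identical(tab$df, c(98L, 44L, 4312L, 565785L, 570239L))
  expect_equal(tab$SS[5], sum(tab$SS[1:4]), tolerance = 1e-6)
})
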