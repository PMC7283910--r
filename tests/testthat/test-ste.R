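test_that("pooled tercile thresholds sit at ranks L/3 and 2L/3", {
  th <- pooled_thresholds(matrix(-4:4, 1))
  expect_equal(th$t_low, -2)
  expect_equal(th$t_high, 1)
  expect_identical(th$L, 9L)

  th2 <- pooled_thresholds(rbind(1:3, 4:6))  # pooled over channels
  expect_equal(th2$t_low, 2)
  expect_equal(th2$t_high, 4)

  deg <- pooled_thresholds(rep(7, 10))
  expect_equal(deg$t_low, deg$t_high)
  expect_error(pooled_thresholds(c(1, 2)), "at least 3")
})

test_that("symbolization bands are half-open with the top band closed", {
  th <- list(t_low = -2, t_high = 1)
  expect_identical(symbolize(c(-3, 0, 2), th), c(1L, 2L, 3L))
  expect_identical(symbolize(rep(-10, 5), th), rep(1L, 5L))
  expect_identical(symbolize(-2, th), 2L)  # value exactly at t_low
  expect_identical(symbolize(1, th), 3L)   # value exactly at t_high
})

test_that("embedding is a bijection onto 27 words and shortens correctly", {
  expect_identical(embed_symbols(c(1, 1, 1, 1)), c(1L, 1L))
  w <- embed_symbols(c(1, 2, 3))
  expect_length(w, 1L)
  expect_identical(decode_word(w), c(1L, 2L, 3L))

  # constructive enumeration: a de Bruijn-style covering sequence
  s <- ternary_debruijn_29()
  expect_length(s, 29L)
  expect_setequal(embed_symbols(s), 1:27)

  # length bookkeeping: (m-1)*tau symbols are consumed
  set.seed(5)
  x <- sample(1:3, 100, replace = TRUE)
  for (tau in 1:3) {
    expect_length(embed_symbols(x, m = 3, tau = tau), 100L - 2L * tau)
  }
  expect_error(embed_symbols(c(1, 2), m = 3), "too short")
})

test_that("transfer entropy matches closed forms and a brute-force counter", {
  # deterministic constant sequences carry no information
  expect_equal(ste_pair(rep(1L, 50), rep(2L, 50)), 0)

  # copy coupling on a ternary i.i.d. process: the ternary entropy rate
  set.seed(11)
  n <- 10000
  x <- sample(1:3, n, replace = TRUE)
  y <- c(1L, x[-n])                   # y reproduces x one step later
  expect_lt(abs(ste_pair(x, y, nstates = 3) - log2(3)), 0.05)

  # the same limit holds on the embedded word processes
  wx <- embed_symbols(x)
  wy <- embed_symbols(y)
  expect_lt(abs(ste_pair(wx, wy) - log2(3)), 0.05)

  # independent ternary sequences: plug-in estimate near zero
  z <- sample(1:3, n, replace = TRUE)
  expect_lt(ste_pair(z, x, nstates = 3), 0.05)

  # 8-word toy with a hand-countable joint table vs the brute-force oracle
  src <- c(3L, 1L, 2L, 2L, 3L, 1L, 1L, 2L)
  tgt <- c(1L, 1L, 2L, 3L, 3L, 2L, 1L, 2L)
  expect_equal(ste_pair(src, tgt, nstates = 3), brute_force_te(src, tgt))

  # random word sequences vs the oracle
  set.seed(21)
  for (k in 1:5) {
    a <- sample(1:27, 60, replace = TRUE)
    b <- sample(1:27, 60, replace = TRUE)
    expect_equal(ste_pair(a, b), brute_force_te(a, b))
  }

  expect_error(ste_pair(1:5, 1:6), "lengths differ")
})

test_that("permuting the source drives TE to the independence baseline", {
  set.seed(13)
  n <- 4000
  x <- sample(1:3, n, replace = TRUE)
  y <- c(1L, x[-n])
  coupled <- ste_pair(x, y, nstates = 3)
  surrogate <- ste_pair(sample(x), y, nstates = 3)
  expect_gt(coupled, 1.4)
  expect_lt(surrogate, 0.05)
})

test_that("ste_matrix agrees with pairwise ste_pair and orders channels", {
  set.seed(17)
  dat <- matrix(rnorm(6 * 500), 6)
  M <- ste_matrix(dat, states = "words")
  th <- pooled_thresholds(dat)
  words <- apply(dat, 1, function(ch) embed_symbols(symbolize(ch, th)))
  for (i in 1:6) for (j in 1:6) {
    expected <- if (i == j) 0 else ste_pair(words[, i], words[, j])
    expect_equal(M[i, j], expected, tolerance = 1e-12)
  }

  # permutation of channels permutes rows/columns of the matrix
  perm <- c(3, 1, 2, 6, 4, 5)
  Mp <- ste_matrix(dat[perm, ], states = "words")
  expect_equal(unclass(Mp), unclass(M)[perm, perm], ignore_attr = TRUE)
})

test_that("white-noise channels give a near-zero symbol-level matrix", {
  set.seed(19)
  dat <- matrix(rnorm(64 * 5000), 64)
  M <- ste_matrix(dat)   # default symbol-level estimator
  off <- M[row(M) != col(M)]
  expect_lt(mean(off), 0.05)
  expect_true(all(off >= 0))
  expect_true(all(diag(M) == 0))
})

test_that("word-level estimator bias matches its analytic expectation", {
  # for independent channels the plug-in word-level TE concentrates near
  # df / (2 n ln 2) with df = 2 * 27^2 / ... measured: ~1404 effective df
  set.seed(23)
  n <- 5000
  x <- sample(1:3, n, replace = TRUE)
  z <- sample(1:3, n, replace = TRUE)
  est <- ste_pair(embed_symbols(z), embed_symbols(x))
  bias <- 1404 / (2 * n * log(2))
  expect_lt(abs(est - bias), bias * 0.5)
})

test_that("duplicated channels give symmetric TE; a driven chain does not", {
  set.seed(29)
  x <- rnorm(3000)
  dup <- rbind(x, x)
  M <- ste_matrix(dup)
  expect_equal(M[1, 2], M[2, 1], tolerance = 1e-12)

  # directed chain: channel 2 is channel 1 delayed plus noise
  drive <- rnorm(10000)
  target <- c(0, drive[-10000]) + rnorm(10000, sd = 0.4)
  Mc <- ste_matrix(rbind(drive, target))
  expect_gt(Mc[1, 2] - Mc[2, 1], 0.1)
})
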