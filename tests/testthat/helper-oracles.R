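# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# exhaustive minimum spanning arborescence by enumeration of parent vectors
brute_force_arborescence <- function(w, root) {
  n <- nrow(w)
  others <- setdiff(seq_len(n), root)
  best <- Inf
  grid <- expand.grid(rep(list(seq_len(n)), length(others)))
  for (k in seq_len(nrow(grid))) {
    par <- rep(NA_integer_, n)
    par[others] <- as.integer(grid[k, ])
    if (any(par[others] == others)) next
    ok <- TRUE
    for (v in others) {
      seen <- integer(0)
      u <- v
      while (!is.na(u) && u != root) {
        if (u %in% seen) { ok <- FALSE; break }
        seen <- c(seen, u)
        u <- par[u]
      }
      if (!ok) break
    }
    if (!ok) next
    tw <- sum(w[cbind(par[others], others)])
    if (!is.na(tw) && tw < best) best <- tw
  }
  best
}

# direct plug-in transfer entropy by explicit frequency tables (source ->
# target, first order), independent of the package's tabulation scheme
brute_force_te <- function(source, target) {
  n <- length(target) - 1L
  trip <- data.frame(xf = target[-1L], xn = target[-length(target)],
                     yn = source[seq_len(n)])
  joint <- stats::aggregate(cnt ~ xf + xn + yn, cbind(trip, cnt = 1), sum)
  p3 <- joint$cnt / n
  total <- 0
  for (r in seq_len(nrow(joint))) {
    xf <- joint$xf[r]; xn <- joint$xn[r]; yn <- joint$yn[r]
    p_xx <- sum(trip$xf == xf & trip$xn == xn) / n
    p_xy <- sum(trip$xn == xn & trip$yn == yn) / n
    p_x <- sum(trip$xn == xn) / n
    total <- total + p3[r] * log2(p3[r] * p_x / (p_xx * p_xy))
  }
  total
}

# ternary de Bruijn-style linear sequence covering all 27 length-3 words
# exactly once: greedy prefer-largest construction, final length 27 + 2
ternary_debruijn_29 <- function() {
  s <- rep(1L, 3L)
  repeat {
    extended <- FALSE
    for (cand in 3L:1L) {
      t <- c(s, cand)
      wins <- sapply(seq_len(length(t) - 2L), function(i) {
        paste(t[i:(i + 2L)], collapse = "")
      })
      if (!anyDuplicated(wins)) { s <- t; extended <- TRUE; break }
    }
    if (!extended) break
  }
  s
}

# a random STE-like matrix: non-negative, asymmetric, zero diagonal
random_ste_like <- function(n = 64L) {
  m <- matrix(stats::runif(n * n, 0, 1.5), n, n)
  diag(m) <- 0
  m
}
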