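#' Euclidean (Frobenius) distance between coupling matrices
#'
#' The square root of the summed squared entry-wise differences over all
#' 64 x 64 entries — the distance used for all brain-network comparisons.
#'
#' @param a,b Matrices of equal shape.
#' @return Non-negative distance.
#' @export
matrix_distance <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (!identical(dim(a), dim(b))) stop("matrix_distance: shape mismatch")
  sqrt(sum((a - b)^2))
}

#' Number of unordered pairs in a group
#'
#' `n * (n - 1) / 2`: 4851 distances among 99 participants, 990 among the
#' 45 task-event conditions.
#'
#' @param n Group size, at least 2.
#' @return Pair count.
#' @export
pair_count <- function(n) {
  if (n < 2L) stop("pair_count: need n >= 2")
  n * (n - 1) / 2
}

#' Between-participant and within-participant distance summaries
#'
#' Computes the two average-Euclidean-distance families. The
#' between-participant group takes, for every unordered pair of
#' participants, the mean Frobenius distance between their coupling
#' matrices over matched (task, event) conditions; the within-participant
#' group takes, for every unordered pair of (task, event) conditions, the
#' mean distance between the two conditions' matrices over participants.
#' The central empirical claim of the fingerprinting approach is that the
#' between-participant mean exceeds the within-participant mean.
#'
#' @param matrices List of [ste_matrix()] objects whose `context`
#'   attributes label participant, task and event. Every participant must
#'   cover the same (task, event) conditions.
#' @return A list with two `distance_summary` entries (`between`, `within`),
#'   each holding `distances`, `mean`, `sd` and `n_pairs`.
#' @export
distance_summaries <- function(matrices) {
  ctx <- lapply(matrices, attr, "context")
  p <- vapply(ctx, function(x) x$participant_id, integer(1))
  cond <- vapply(ctx, function(x) paste(x$task, x$event, sep = "."), character(1))
  parts <- sort(unique(p))
  conds <- sort(unique(cond))
  if (length(parts) < 2L) stop("distance_summaries: need at least 2 participants")
  if (length(conds) < 2L) stop("distance_summaries: need at least 2 conditions")
  lookup <- function(pp, cc) {
    i <- which(p == pp & cond == cc)
    if (length(i) != 1L) {
      stop("distance_summaries: participant ", pp, " condition ", cc,
           " appears ", length(i), " times")
    }
    matrices[[i]]
  }
  between <- numeric(0)
  for (a in seq_along(parts)) for (b in seq_len(a - 1L)) {
    d <- vapply(conds, function(cc) {
      matrix_distance(lookup(parts[a], cc), lookup(parts[b], cc))
    }, numeric(1))
    between <- c(between, mean(d))
  }
  within <- numeric(0)
  for (a in seq_along(conds)) for (b in seq_len(a - 1L)) {
    d <- vapply(parts, function(pp) {
      matrix_distance(lookup(pp, conds[a]), lookup(pp, conds[b]))
    }, numeric(1))
    within <- c(within, mean(d))
  }
  mk <- function(x, label) {
    structure(list(group = label, distances = x, mean = mean(x),
                   sd = stats::sd(x), n_pairs = length(x)),
              class = "distance_summary")
  }
  list(between = mk(between, "between_participants"),
       within = mk(within, "between_events/tasks"))
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("<distance_summary> %s: mean %.3f, sd %.3f over %d pairs\n",
              x$group, x$mean, x$sd, x$n_pairs))
  invisible(x)
}

#' Two-sample z-test from group summaries
#'
#' \eqn{z = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}, with one- and
#' two-tailed p-values from the standard normal and the critical values at
#' the chosen level (2.326 one-tailed and 2.576 two-tailed at alpha 0.01).
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param alpha Significance level.
#' @return A list with `z`, `p_one_tailed`, `p_two_tailed`,
#'   `crit_one_tailed`, `crit_two_tailed` and `alpha`.
#' @export
#' @examples
#' two_sample_ztest(5, 1, 100, 4, 1, 100)$z   # 7.071068
two_sample_ztest <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.01) {
  if (n1 < 2L || n2 < 2L) stop("two_sample_ztest: need n >= 2 in each group")
  if (sd1 <= 0 || sd2 <= 0) stop("two_sample_ztest: zero variance group")
  z <- (mean1 - mean2) / sqrt(sd1^2 / n1 + sd2^2 / n2)
  list(z = z,
       p_one_tailed = stats::pnorm(abs(z), lower.tail = FALSE),
       p_two_tailed = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       crit_one_tailed = stats::qnorm(1 - alpha),
       crit_two_tailed = stats::qnorm(1 - alpha / 2),
       alpha = alpha)
}

#' Balanced two-way ANOVA with replication on a stacked layout
#'
#' Fixed-effects two-way analysis of variance for the cohort spectrum
#' layout: a matrix whose columns are the levels of the column factor
#' (participants) and whose rows stack `n_replicates` consecutive
#' replicates for each level of the row factor (task-event conditions) —
#' e.g. the 5760 x 99 layout of 45 conditions x 128 spectrum components
#' per 99 participants. Sums of squares use the closed-form balanced
#' decomposition (columns + rows + interaction + error = total).
#'
#' @param data Numeric matrix, `n_row_levels * n_replicates` rows by
#'   `n_column_levels` columns.
#' @param n_row_levels Number of row-factor levels.
#' @param n_replicates Replicates per (row level, column) cell.
#' @return An `anova_table` data frame with SS, df, MS, F and p per source.
#' @export
two_way_anova <- function(data, n_row_levels,
                          n_replicates = nrow(data) / n_row_levels) {
  data <- as.matrix(data)
  r <- as.integer(n_row_levels)
  reps <- n_replicates
  if (reps != as.integer(reps) || r * as.integer(reps) != nrow(data)) {
    stop("two_way_anova: row count ", nrow(data),
         " is not n_row_levels x n_replicates")
  }
  reps <- as.integer(reps)
  cc <- ncol(data)
  N <- length(data)
  grand <- mean(data)

  row_lvl <- rep(seq_len(r), each = reps)
  col_means <- colMeans(data)
  row_means <- as.numeric(rowsum(data, row_lvl) %*% rep(1, cc)) / (reps * cc)
  cell_means <- rowsum(data, row_lvl) / reps          # r x c

  ss_col <- r * reps * sum((col_means - grand)^2)
  ss_row <- cc * reps * sum((row_means - grand)^2)
  ss_cell <- reps * sum((cell_means - grand)^2)
  ss_int <- ss_cell - ss_col - ss_row
  ss_tot <- sum((data - grand)^2)
  ss_err <- ss_tot - ss_cell

  df_col <- cc - 1L
  df_row <- r - 1L
  df_int <- df_col * df_row
  df_err <- r * cc * (reps - 1L)
  df_tot <- N - 1L

  ms <- c(ss_col / df_col, ss_row / df_row, ss_int / df_int, ss_err / df_err)
  f <- ms[1:3] / ms[4L]
  p <- stats::pf(f, c(df_col, df_row, df_int), df_err, lower.tail = FALSE)

  out <- data.frame(
    source = c("Columns", "Rows", "Interaction", "Error", "Total"),
    SS = c(ss_col, ss_row, ss_int, ss_err, ss_tot),
    df = c(df_col, df_row, df_int, df_err, df_tot),
    MS = c(ms, NA),
    F = c(f, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Two-way ANOVA (balanced, with replication)\n")
  print.data.frame(format(x, digits = 6), row.names = FALSE)
  invisible(x)
}
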