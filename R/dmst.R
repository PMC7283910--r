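#' Weighted digraph from a coupling matrix
#'
#' Turns an [ste_matrix()] into the weighted digraph whose minimum spanning
#' arborescence is the directed brain network. `mode = "literal"` uses the
#' transfer-entropy values directly as distances (minimizing summed TE);
#' `mode = "negate"` uses their negatives so the minimum arborescence
#' maximizes total information flow. The mode is recorded on the result.
#'
#' @param m Square numeric matrix; the diagonal is ignored.
#' @param mode `"literal"` or `"negate"`.
#' @return A `weighted_digraph`: list with `n`, a `weights` matrix (`NA`
#'   for absent edges and the diagonal) and `mode`.
#' @export
from_ste <- function(m, mode = c("literal", "negate")) {
  mode <- match.arg(mode)
  w <- unclass(m)
  attr(w, "context") <- NULL
  if (nrow(w) != ncol(w)) stop("from_ste: matrix must be square")
  if (any(!is.finite(w))) stop("from_ste: non-finite weights")
  if (mode == "negate") w <- -w
  diag(w) <- NA_real_
  structure(list(n = nrow(w), weights = w, mode = mode),
            class = "weighted_digraph")
}

#' Minimum spanning arborescence (Chu-Liu/Edmonds)
#'
#' Finds the spanning arborescence of minimum total weight rooted at `root`:
#' every node except the root receives exactly one incoming edge, the edges
#' form no cycle, and every node is reachable from the root. The algorithm
#' repeatedly selects the cheapest incoming edge of each non-root node,
#' contracts any cycle into a super-node with entering-edge weights reduced
#' by the weight of the cycle edge they displace, and expands contractions
#' by dropping the displaced cycle edge (the breaking-loop step). Ties among
#' equal-weight entering edges go to the lowest source index, making the
#' result deterministic for a given root.
#'
#' @param graph A [from_ste()] digraph, or a square weight matrix
#'   (`NA` = absent edge).
#' @param root Root node index, an electrode label, or `"random"` for a
#'   seeded random choice.
#' @param seed Seed used when `root = "random"`.
#' @return An `arborescence`: list with `root`, a `parent` vector (`NA` at
#'   the root), `weights` of the chosen edges (original scale),
#'   `total_weight` and the digraph `mode`.
#' @export
#' @examples
#' w <- matrix(c(NA, 1, 1, 9, NA, 1, 9, 1, NA), 3, 3, byrow = TRUE)
#' minimum_arborescence(w, root = 1)
minimum_arborescence <- function(graph, root = "random", seed = NULL) {
  if (inherits(graph, "weighted_digraph")) {
    w <- graph$weights
    mode <- graph$mode
  } else {
    w <- as.matrix(graph)
    diag(w) <- NA_real_
    mode <- "literal"
  }
  n <- nrow(w)
  labels <- rownames(w)
  if (identical(root, "random")) {
    root <- .seeded_sample(n, seed)
  } else if (is.character(root)) {
    root <- if (!is.null(labels) && root %in% labels) match(root, labels)
            else channel_index(root)
  }
  root <- as.integer(root)
  stopifnot(root >= 1L, root <= n)

  # edge list: from, to, weight
  idx <- which(!is.na(w), arr.ind = TRUE)
  edges <- data.frame(from = idx[, 1L], to = idx[, 2L],
                      w = w[idx], id = seq_len(nrow(idx)))
  chosen <- .edmonds(edges, seq_len(n), root)
  parent <- rep(NA_integer_, n)
  wts <- rep(NA_real_, n)
  parent[edges$to[chosen]] <- edges$from[chosen]
  wts[edges$to[chosen]] <- edges$w[chosen]

  # structural invariants
  if (sum(!is.na(parent)) != n - 1L || !is.na(parent[root])) {
    stop("minimum_arborescence: internal error, malformed tree")
  }
  structure(list(root = root, parent = parent, weights = wts,
                 total_weight = sum(wts, na.rm = TRUE), mode = mode,
                 labels = labels),
            class = "arborescence")
}

.seeded_sample <- function(n, seed) {
  if (is.null(seed)) return(sample.int(n, 1L))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(n, 1L)
}

# Recursive Chu-Liu/Edmonds on an edge list; returns row indices of `edges`
# forming the minimum arborescence. `nodes` is the set of active node ids
# (super-nodes get fresh ids on contraction); root excluded from entry.
.edmonds <- function(edges, nodes, root) {
  # cheapest incoming edge per non-root node; ties -> lowest source index
  ord <- order(edges$to, edges$w, edges$from)
  e <- edges[ord, , drop = FALSE]
  first <- !duplicated(e$to)
  enter <- e[first & e$to != root, , drop = FALSE]
  missing <- setdiff(setdiff(nodes, root), enter$to)
  if (length(missing)) {
    stop("minimum_arborescence: node(s) unreachable from root: ",
         paste(missing, collapse = ", "))
  }

  # cycle detection in the chosen-entry functional graph
  n_max <- max(nodes)
  pred <- rep(NA_integer_, n_max)
  pred[enter$to] <- enter$from
  color <- integer(n_max)  # 0 unseen, 1 in progress, 2 done
  cycle <- NULL
  for (v in nodes) {
    if (color[v] != 0L) next
    path <- integer(0)
    u <- v
    while (!is.na(u) && color[u] == 0L) {
      color[u] <- 1L
      path <- c(path, u)
      u <- pred[u]
    }
    if (!is.na(u) && color[u] == 1L) {
      cycle <- path[seq.int(match(u, path), length(path))]
      break
    }
    color[path] <- 2L
  }
  if (is.null(cycle)) return(match(enter$id, edges$id))

  # contract the cycle into super-node `super`
  super <- n_max + 1L
  in_cyc <- rep(FALSE, n_max)
  in_cyc[cycle] <- TRUE
  enter_w <- rep(NA_real_, n_max)
  enter_w[enter$to] <- enter$w
  enter_id <- rep(NA_integer_, n_max)
  enter_id[enter$to] <- enter$id

  keep <- !(in_cyc[edges$from] & in_cyc[edges$to])
  ne <- edges[keep, , drop = FALSE]
  into <- in_cyc[ne$to]
  # entering edges: weight reduced by the displaced cycle edge's weight
  ne$w[into] <- ne$w[into] - enter_w[ne$to[into]]
  ne$to[into] <- super
  ne$from[in_cyc[ne$from]] <- super

  sub <- .edmonds(ne, c(setdiff(nodes, cycle), super), root)
  chosen_ids <- ne$id[sub]

  # expansion: find which original edge enters the cycle, drop the cycle
  # edge it displaces, keep the remaining cycle edges
  entering <- chosen_ids[ne$to[sub] == super]
  cyc_edge_ids <- enter_id[cycle]
  if (length(entering) == 1L) {
    v_star <- edges$to[match(entering, edges$id)]
    cyc_edge_ids <- cyc_edge_ids[cycle != v_star]
  } else {
    stop("minimum_arborescence: internal error in cycle expansion")
  }
  match(c(chosen_ids, cyc_edge_ids), edges$id)
}

#' @export
print.arborescence <- function(x, ...) {
  lab <- function(i) if (!is.null(x$labels)) x$labels[i] else i
  cat(sprintf("<arborescence> %d nodes, root %s, total weight %.4f (mode %s)\n",
              length(x$parent), lab(x$root), x$total_weight, x$mode))
  invisible(x)
}

#' Out-degree profile and key node of a brain network
#'
#' Tabulates the out-degree of every node of an arborescence; the key node
#' is the node (or tie set) with the largest out-degree, reported with its
#' electrode label when a montage is attached.
#'
#' @param tree An [minimum_arborescence()] result.
#' @param channels Optional [channel_map()] for labels.
#' @return A list with a `degrees` data frame (`node`, `label`,
#'   `out_degree`) and `key_node` (integer vector, ties included).
#' @export
out_degree_profile <- function(tree, channels = NULL) {
  n <- length(tree$parent)
  deg <- tabulate(tree$parent[!is.na(tree$parent)], nbins = n)
  labs <- if (!is.null(channels)) as.character(channels)
          else if (!is.null(tree$labels)) tree$labels
          else as.character(seq_len(n))
  key <- which(deg == max(deg))
  list(degrees = data.frame(node = seq_len(n), label = labs,
                            out_degree = deg, stringsAsFactors = FALSE),
       key_node = key, key_label = labs[key])
}

#' Export an arborescence as a TSV edge list or DOT graph
#'
#' @param tree An [minimum_arborescence()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_arborescence <- function(tree, path) {
  to <- which(!is.na(tree$parent))
  df <- data.frame(source = tree$parent[to], target = to,
                   weight = tree$weights[to])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_arborescence
#' @export
write_arborescence_dot <- function(tree, path) {
  lab <- function(i) if (!is.null(tree$labels)) tree$labels[i] else i
  to <- which(!is.na(tree$parent))
  lines <- c("digraph brain_network {",
             sprintf('  "%s" [shape=doublecircle];', lab(tree$root)),
             sprintf('  "%s" -> "%s" [label="%.3g"];',
                     lab(tree$parent[to]), lab(to), tree$weights[to]),
             "}")
  writeLines(lines, path)
  invisible(path)
}
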