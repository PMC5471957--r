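#' @useDynLib atria, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Walk-product upper bounds on the signed double cover.
#
# Vertices 1..n are the "even" copies, n+1..2n the "odd" copies; a positive
# edge (u,v) connects copies of equal parity, a negative edge copies of
# opposite parity, each with length -log|w|.  Shortest even-copy -> even-copy
# distance then bounds (from above) the magnitude of any positive-product
# walk between u and v, and even -> odd any negative-product walk.  Walks are
# a superset of simple paths, so these are sound pruning bounds for the exact
# search.
walk_bounds <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  pos <- w > 0
  from <- c(el[pos, 1L], el[pos, 1L] + n, el[!pos, 1L], el[!pos, 1L] + n)
  to   <- c(el[pos, 2L], el[pos, 2L] + n, el[!pos, 2L] + n, el[!pos, 2L])
  dw <- -log(abs(c(w[pos], w[pos], w[!pos], w[!pos])))
  cover <- igraph::make_empty_graph(n = 2L * n, directed = FALSE)
  if (length(from))
    cover <- igraph::add_edges(cover, rbind(from, to))
  D <- igraph::distances(cover, v = seq_len(n), to = seq_len(2L * n),
                         weights = if (length(from)) dw else NULL)
  list(pos = exp(-D[, seq_len(n), drop = FALSE]),
       neg = exp(-D[, n + seq_len(n), drop = FALSE]))
}

# A signed graph is balanced when no cycle has an odd number of negative
# edges; equivalently, when no vertex's even and odd double-cover copies are
# connected, i.e. the diagonal of the negative bound matrix is all zero.
# On a balanced graph every path between a fixed pair has the same sign and
# deleting a cycle from a walk never shrinks the product (|w| <= 1), so the
# walk bounds are attained by simple paths and ARE the exact labels.
balanced_from_bounds <- function(bounds) all(diag(bounds$neg) == 0)

gain_loss_engine <- function(g, source_idx, bounds, el = NULL) {
  if (balanced_from_bounds(bounds)) {
    gain <- bounds$pos[source_idx, ]
    gain[source_idx] <- 0
    return(list(gain = gain, loss = -bounds$neg[source_idx, ]))
  }
  n <- igraph::vcount(g)
  if (is.null(el)) el <- igraph::as_edgelist(g, names = FALSE)
  .gain_loss_cpp(n, as.integer(el[, 1L] - 1L), as.integer(el[, 2L] - 1L),
                 igraph::E(g)$weight, as.integer(source_idx - 1L),
                 bounds$pos, bounds$neg)
}

#' Maximum-gain and maximum-loss path products from one node
#'
#' For a source node `i`, `gain[j]` is the largest *positive* product of edge
#' weights over all simple paths from `i` to `j` (0 when no path has a
#' positive product) and `loss[j]` is the most negative such product (0 when
#' none is negative).  A path with an even number of negative edges yields a
#' gain, an odd number a loss; the engine propagates both labels
#' simultaneously, a positive edge preserving gain/loss and a negative edge
#' swapping them.  Results are exact with respect to the simple-path
#' definition (see [brute_force_gain_loss()]).
#'
#' @param graph a signed graph.
#' @param source node identifier.
#' @return an object of class `gain_loss`: a list with elements `source`,
#'   `gain` and `loss` (named numeric vectors over all nodes; the source's
#'   own entries are 0).
#' @examples
#' g <- signed_graph(data.frame(from = c("A", "C", "A", "B"),
#'                              to = c("C", "D", "B", "C"),
#'                              weight = c(0.2, -0.5, -0.8, 0.7)))
#' gl <- gain_loss_from(g, "A")
#' gl$gain[["D"]]   # 0.28 via A-B-C-D
#' gl$loss[["D"]]   # -0.1 via A-C-D
#' @export
gain_loss_from <- function(graph, source) {
  g <- as_signed_graph(graph)
  nm <- igraph::V(g)$name
  idx <- match(source, nm)
  if (is.na(idx)) stop("node not in graph: ", source)
  res <- gain_loss_engine(g, idx, walk_bounds(g))
  structure(list(source = source,
                 gain = stats::setNames(res$gain, nm),
                 loss = stats::setNames(res$loss, nm)),
            class = "gain_loss")
}

#' Exhaustive gain/loss oracle over all simple paths
#'
#' Enumerates every simple path from `source` and records, per target, the
#' maximum positive and minimum negative edge-weight product.  Ground truth
#' for [gain_loss_from()] by construction; guarded by a node-count cap
#' because enumeration is combinatorial.
#'
#' @param graph a signed graph.
#' @param source node identifier.
#' @param max_nodes refuse graphs larger than this (default 10).
#' @return a `gain_loss` object, as [gain_loss_from()].
#' @export
brute_force_gain_loss <- function(graph, source, max_nodes = 10L) {
  g <- as_signed_graph(graph)
  n <- igraph::vcount(g)
  if (n > max_nodes)
    stop("graph has ", n, " nodes; brute force is capped at ", max_nodes,
         " (raise `max_nodes` deliberately if you must)")
  nm <- igraph::V(g)$name
  src <- match(source, nm)
  if (is.na(src)) stop("node not in graph: ", source)
  adj <- lapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    ids <- igraph::get_edge_ids(g, rbind(rep(v, length(nb)), nb))
    list(nb = nb, w = igraph::E(g)$weight[ids])
  })
  gain <- numeric(n)
  loss <- numeric(n)
  visited <- logical(n)
  recurse <- function(v, prod) {
    a <- adj[[v]]
    for (k in seq_along(a$nb)) {
      u <- a$nb[k]
      if (visited[u]) next
      p2 <- prod * a$w[k]
      if (p2 > 0) {
        if (p2 > gain[u]) gain[u] <<- p2
      } else if (p2 < loss[u]) loss[u] <<- p2
      visited[u] <<- TRUE
      recurse(u, p2)
      visited[u] <<- FALSE
    }
  }
  visited[src] <- TRUE
  recurse(src, 1)
  structure(list(source = source,
                 gain = stats::setNames(gain, nm),
                 loss = stats::setNames(loss, nm)),
            class = "gain_loss")
}

#' Payoff vector of a signed graph
#'
#' Each node's signed pay is the sum over all other nodes of gain plus loss
#' path products; the pay (the centrality the iterative procedure maximizes)
#' is its magnitude:
#' \deqn{u_i = | \sum_{j \ne i} G(i,j) + L(i,j) |.}
#' Disconnected pairs contribute exactly 0, so pay is finite and bounded by
#' `n - 1`.
#'
#' @param graph a signed graph.
#' @return an object of class `pay_vector`: list with named numeric vectors
#'   `pay` (nonnegative) and `signed_pay`.
#' @export
pay_vector <- function(graph) {
  g <- as_signed_graph(graph)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  signed <- numeric(n)
  if (igraph::ecount(g) > 0L) {
    bounds <- walk_bounds(g)
    if (balanced_from_bounds(bounds)) {
      # closed form: row sums of the cover bounds (minus the self term)
      signed <- rowSums(bounds$pos) - 1 - rowSums(bounds$neg)
    } else {
      el <- igraph::as_edgelist(g, names = FALSE)
      deg <- igraph::degree(g)
      for (i in seq_len(n)) {
        if (deg[i] == 0L) next
        res <- gain_loss_engine(g, i, bounds, el)
        signed[i] <- sum(res$gain) + sum(res$loss)
      }
    }
  }
  structure(list(pay = stats::setNames(abs(signed), nm),
                 signed_pay = stats::setNames(signed, nm)),
            class = "pay_vector")
}

#' @export
print.gain_loss <- function(x, ...) {
  cat("Gain/loss path products from node", x$source, "\n")
  print(data.frame(node = names(x$gain), gain = unname(x$gain),
                   loss = unname(x$loss)), row.names = FALSE)
  invisible(x)
}

#' @export
print.pay_vector <- function(x, ...) {
  cat("Pay vector over", length(x$pay), "nodes\n")
  print(data.frame(node = names(x$pay), pay = unname(x$pay),
                   signed_pay = unname(x$signed_pay)), row.names = FALSE)
  invisible(x)
}
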