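#' Weighted degree centrality
#'
#' The signed sum of incident edge weights, so a villain (many strong
#' negative edges) scores low/negative rather than high.  Set
#' `absolute = TRUE` to sum magnitudes instead.
#'
#' @param graph a signed graph.
#' @param absolute sum `|w|` instead of `w`.
#' @return an object of class `centrality_scores`: list with `algorithm` and
#'   a named numeric `score` vector.
#' @export
weighted_degree <- function(graph, absolute = FALSE) {
  g <- as_signed_graph(graph)
  w <- igraph::E(g)$weight
  if (absolute) w <- abs(w)
  s <- igraph::strength(g, weights = if (igraph::ecount(g)) w else NA)
  if (!igraph::ecount(g)) s <- stats::setNames(numeric(igraph::vcount(g)),
                                               igraph::V(g)$name)
  centrality_scores(if (absolute) "degree_abs" else "degree", s)
}

#' Transform signed weights into nonnegative distances
#'
#' Replaces every weight `w` by `-log|w| >= 0`, so that larger edge
#' magnitudes carry smaller distances and maximum-|product| paths coincide
#' with minimum-sum shortest paths.  `|w| = 1` maps to distance 0.
#'
#' @param graph a signed graph.
#' @return an igraph object whose `weight` attribute holds the distances
#'   (no longer a signed graph: weights are nonnegative, possibly > 1).
#' @export
distance_transform <- function(graph) {
  g <- as_signed_graph(graph)
  if (igraph::ecount(g))
    igraph::E(g)$weight <- -log(abs(igraph::E(g)$weight))
  g
}

#' Closeness centrality on the distance transform
#'
#' Reciprocal of the summed shortest-path distances to the reachable
#' vertices (disconnected pairs contribute nothing).  Isolated nodes score 0
#' so that all scores are finite.
#'
#' @param graph a signed graph.
#' @return a `centrality_scores` object.
#' @export
closeness_centrality <- function(graph) {
  g <- distance_transform(graph)
  s <- suppressWarnings(
    igraph::closeness(g, mode = "all",
                      weights = if (igraph::ecount(g)) igraph::E(g)$weight
                                else NA))
  s[!is.finite(s)] <- 0
  centrality_scores("closeness", stats::setNames(as.numeric(s),
                                                 igraph::V(g)$name))
}

#' Betweenness centrality on the distance transform
#'
#' Fraction of shortest paths through each node, equal-length paths counted
#' with even splitting, distances being `-log|w|`.
#'
#' @param graph a signed graph.
#' @return a `centrality_scores` object.
#' @export
betweenness_centrality <- function(graph) {
  g <- distance_transform(graph)
  s <- igraph::betweenness(g, directed = FALSE,
                           weights = if (igraph::ecount(g))
                             igraph::E(g)$weight else NA)
  centrality_scores("betweenness", stats::setNames(as.numeric(s),
                                                   igraph::V(g)$name))
}

centrality_scores <- function(algorithm, score) {
  stopifnot(is.numeric(score), !is.null(names(score)), all(is.finite(score)))
  structure(list(algorithm = algorithm, score = score),
            class = "centrality_scores")
}

#' @export
print.centrality_scores <- function(x, ...) {
  cat("Centrality scores (", x$algorithm, ")\n", sep = "")
  print(data.frame(node = names(x$score), score = unname(x$score)),
        row.names = FALSE)
  invisible(x)
}

#' Compare all centrality algorithms on one graph
#'
#' One column per algorithm; the ATria column reports each node's pay at its
#' iteration of selection (0 for never-selected nodes).
#'
#' @param graph a signed graph.
#' @return a data frame with columns `node`, `atria`, `degree`, `closeness`,
#'   `betweenness`, in lexicographic node order.
#' @export
centrality_table <- function(graph) {
  g <- as_signed_graph(graph)
  nodes <- lex_sort(igraph::V(g)$name)
  rk <- atria_rank(g)
  at <- stats::setNames(rk$pay, rk$node)[nodes]
  data.frame(node = nodes,
             atria = unname(at),
             degree = unname(weighted_degree(g)$score[nodes]),
             closeness = unname(closeness_centrality(g)$score[nodes]),
             betweenness = unname(betweenness_centrality(g)$score[nodes]),
             stringsAsFactors = FALSE)
}
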