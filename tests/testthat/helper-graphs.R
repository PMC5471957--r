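# Shared fixtures, all built in code.

# The worked 4-node example with mixed signs: two A-D routes, one a gain
# (A-B-C-D, product 0.28) and one a loss (A-C-D, product -0.1).
worked_example_graph <- function() {
  signed_graph(data.frame(from = c("A", "C", "A", "B"),
                          to = c("C", "D", "B", "C"),
                          weight = c(0.2, -0.5, -0.8, 0.7)))
}

# Erdos-Renyi signed graph; weights uniform on [-1,1] with zeros nudged off.
random_signed_graph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  if (igraph::ecount(g) > 0L) {
    w <- stats::runif(igraph::ecount(g), -1, 1)
    w[w == 0] <- 0.5
    igraph::E(g)$weight <- w
  }
  g
}

# Balanced variant: signs induced by a random two-camp assignment, so every
# cycle has an even number of negative edges.
random_balanced_graph <- function(n, p = 0.5, seed = 1) {
  g <- random_signed_graph(n, p, seed)
  set.seed(seed + 10000L)
  camp <- sample(c(-1, 1), n, replace = TRUE)
  if (igraph::ecount(g) > 0L) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$weight <- abs(igraph::E(g)$weight) *
      camp[el[, 1L]] * camp[el[, 2L]]
  }
  g
}

# Independent all-pairs shortest-path oracle (Floyd-Warshall) on -log|w|
# distances, for checking the igraph-backed baselines.
brute_shortest_paths <- function(g) {
  n <- igraph::vcount(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  d <- -log(abs(igraph::E(g)$weight))
  for (e in seq_len(nrow(el))) {
    D[el[e, 1L], el[e, 2L]] <- d[e]
    D[el[e, 2L], el[e, 1L]] <- d[e]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  dimnames(D) <- list(igraph::V(g)$name, igraph::V(g)$name)
  D
}
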