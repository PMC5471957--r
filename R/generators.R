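#' Synthetic signed-network generators
#'
#' Each generator is a pure function of its parameters and `seed`: the same
#' call yields byte-identical graphs.  All return a list with elements
#' `graph` (a validated signed graph) and `spec` (a `generator_spec`
#' recording the family, parameters, seed and the planted role of every
#' node), so that qualitative claims — leader first, villain negative,
#' bridges nonzero — can be tested without external data.
#'
#' @name generators
NULL

generator_spec <- function(family, params, seed, roles) {
  structure(list(family = family, params = params, seed = seed,
                 roles = roles),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("Generator:", x$family, "(seed", x$seed, ")\n")
  utils::str(x$params, give.attr = FALSE)
  cat("roles:", paste(sprintf("%s=%d", names(table(x$roles)),
                              as.integer(table(x$roles))), collapse = ", "),
      "\n")
  invisible(x)
}

check_range <- function(r, what, positive = TRUE) {
  if (length(r) != 2L || r[1L] > r[2L])
    stop(what, " must be an increasing range of length 2")
  if (positive && (r[1L] <= 0 || r[2L] > 1))
    stop(what, " must lie in (0, 1]")
  if (!positive && (r[2L] >= 0 || r[1L] < -1))
    stop(what, " must lie in [-1, 0)")
  r
}

runif_range <- function(n, r) stats::runif(n, r[1L], r[2L])

clique_edges <- function(ids, weights_fun) {
  pairs <- utils::combn(ids, 2L)
  data.frame(from = pairs[1L, ], to = pairs[2L, ],
             weight = weights_fun(ncol(pairs)), stringsAsFactors = FALSE)
}

#' Weighted clique with a planted leader
#'
#' A complete positive-weight graph in which one node's incident edges are
#' drawn from a strictly higher range than everyone else's mutual edges —
#' the dominant member of a club.
#'
#' @param n clique size (>= 3), leader included.
#' @param leader_w,member_w positive weight ranges `c(lo, hi)`; the leader
#'   range must lie strictly above the member range.
#' @param seed integer RNG seed.
#' @return list with `graph` and `spec` (roles: one `leader`, rest `member`).
#' @export
clique_with_leader <- function(n = 4, leader_w = c(0.9, 0.95),
                               member_w = c(0.7, 0.8), seed = 1) {
  if (n < 3L) stop("n must be at least 3")
  check_range(leader_w, "leader_w")
  check_range(member_w, "member_w")
  if (leader_w[1L] <= member_w[2L])
    stop("leader_w must lie strictly above member_w")
  leader <- "L"
  members <- sprintf("m%02d", seq_len(n - 1L))
  edges <- withr::with_seed(seed, {
    e1 <- data.frame(from = leader, to = members,
                     weight = runif_range(n - 1L, leader_w))
    e2 <- if (n > 2L) clique_edges(members,
                                   function(k) runif_range(k, member_w))
    rbind(e1, e2)
  })
  roles <- stats::setNames(c("leader", rep("member", n - 1L)),
                           c(leader, members))
  list(graph = signed_graph(edges),
       spec = generator_spec("clique_with_leader",
                             list(n = n, leader_w = leader_w,
                                  member_w = member_w), seed, roles))
}

#' Positive clique plus a planted villain
#'
#' `n` members form a complete positive clique; one extra node connects to
#' every member with a strong negative weight — the common enemy.
#'
#' @param n size of the positive clique (>= 2), villain excluded.
#' @param villain_w negative weight range `c(lo, hi)`, e.g. `c(-0.95, -0.9)`.
#' @param member_w positive weight range for intra-clique edges.
#' @param seed integer RNG seed.
#' @return list with `graph` and `spec` (roles: one `villain`, rest `member`).
#' @export
clique_with_villain <- function(n = 4, villain_w = c(-0.95, -0.9),
                                member_w = c(0.7, 0.8), seed = 1) {
  if (n < 2L) stop("n must be at least 2")
  check_range(villain_w, "villain_w", positive = FALSE)
  check_range(member_w, "member_w")
  if (abs(villain_w[2L]) <= member_w[2L])
    stop("villain edges must be stronger in magnitude than member edges")
  villain <- "V"
  members <- sprintf("m%02d", seq_len(n))
  edges <- withr::with_seed(seed, {
    rbind(clique_edges(members, function(k) runif_range(k, member_w)),
          data.frame(from = villain, to = members,
                     weight = runif_range(n, villain_w)))
  })
  roles <- stats::setNames(c(rep("member", n), "villain"),
                           c(members, villain))
  list(graph = signed_graph(edges),
       spec = generator_spec("clique_with_villain",
                             list(n = n, villain_w = villain_w,
                                  member_w = member_w), seed, roles))
}

#' Clique of rival groups
#'
#' A complete graph over two groups with uniform weight `+w` inside each
#' group and `-w` across — every node is simultaneously a leader to its own
#' group and a villain to the other.
#'
#' @param group_sizes integer vector of length 2.
#' @param w weight magnitude in (0, 1].
#' @param seed kept for interface uniformity (the construction is
#'   deterministic).
#' @return list with `graph` and `spec` (roles: `member`, with the group in
#'   `spec$params$groups`).
#' @export
rival_groups <- function(group_sizes = c(2, 2), w = 0.8, seed = 1) {
  if (length(group_sizes) != 2L || any(group_sizes < 1L))
    stop("group_sizes must be two positive integers")
  if (w <= 0 || w > 1) stop("w must lie in (0, 1]")
  g1 <- sprintf("A%02d", seq_len(group_sizes[1L]))
  g2 <- sprintf("B%02d", seq_len(group_sizes[2L]))
  pairs <- utils::combn(c(g1, g2), 2L)
  same <- (pairs[1L, ] %in% g1) == (pairs[2L, ] %in% g1)
  edges <- data.frame(from = pairs[1L, ], to = pairs[2L, ],
                      weight = ifelse(same, w, -w))
  roles <- stats::setNames(rep("member", length(c(g1, g2))), c(g1, g2))
  list(graph = signed_graph(edges),
       spec = generator_spec("rival_groups",
                             list(group_sizes = group_sizes, w = w,
                                  groups = list(g1, g2)), seed, roles))
}

#' Two positive triads joined by one connector edge
#'
#' Triangles `{A,B,C}` and `{D,E,F}` with positive intra-triad weights and a
#' single connector edge joining C and E.  B (resp. D) is the local leader:
#' its two incident edges are drawn from the upper third of the triad's
#' weight range while the remaining edge comes from the lower third, so the
#' leader's margin over its triad mates is at least a third of the range
#' width for every seed.  With the default weak connector (0.1) that margin
#' provably exceeds the relay benefit the bridge endpoints draw from the
#' connector, so the two leaders are always extracted first.
#'
#' @param intra1,intra2 positive weight ranges for the two triads;
#'   `intra1` must lie strictly above `intra2`.
#' @param connector_w connector weight in `[-1,1]`, nonzero; the default 0.1
#'   is weaker than every triad edge.
#' @param seed integer RNG seed.
#' @return list with `graph` and `spec` (roles: `leader` for B and D,
#'   `bridge` for C and E, `member` otherwise).
#' @export
two_triads <- function(intra1 = c(0.85, 0.95), intra2 = c(0.7, 0.8),
                       connector_w = 0.1, seed = 1) {
  check_range(intra1, "intra1")
  check_range(intra2, "intra2")
  if (intra1[1L] <= intra2[2L])
    stop("intra1 must lie strictly above intra2")
  if (connector_w == 0 || abs(connector_w) > 1)
    stop("connector_w must be nonzero with magnitude <= 1")
  triad <- function(ids, r, leader) {
    third <- diff(r) / 3
    w <- c(sort(stats::runif(2L, r[2L] - third, r[2L]), decreasing = TRUE),
           stats::runif(1L, r[1L], r[1L] + third))
    others <- setdiff(ids, leader)
    data.frame(from = c(leader, leader, others[1L]),
               to = c(others[1L], others[2L], others[2L]),
               weight = w)  # leader carries the two strongest edges
  }
  edges <- withr::with_seed(seed, {
    rbind(triad(c("A", "B", "C"), intra1, "B"),
          triad(c("D", "E", "F"), intra2, "D"),
          data.frame(from = "C", to = "E", weight = connector_w))
  })
  roles <- c(A = "member", B = "leader", C = "bridge",
             D = "leader", E = "bridge", F = "member")
  list(graph = signed_graph(edges),
       spec = generator_spec("two_triads",
                             list(intra1 = intra1, intra2 = intra2,
                                  connector_w = connector_w), seed, roles))
}

#' Two disjoint cliques with random positive weights
#'
#' Complete graphs of sizes `n1` and `n2`, i.i.d. uniform (0,1) weights, no
#' connecting edges.
#'
#' @param n1,n2 clique sizes (>= 2).
#' @param seed integer RNG seed.
#' @return list with `graph` and `spec`; `spec$params$cliques` holds the two
#'   node-id vectors.
#' @export
two_cliques <- function(n1 = 10, n2 = 100, seed = 1) {
  if (n1 < 2L || n2 < 2L) stop("clique sizes must be at least 2")
  c1 <- sprintf("a%03d", seq_len(n1))
  c2 <- sprintf("b%03d", seq_len(n2))
  edges <- withr::with_seed(seed, {
    rbind(clique_edges(c1, stats::runif),
          clique_edges(c2, stats::runif))
  })
  roles <- stats::setNames(rep("member", n1 + n2), c(c1, c2))
  list(graph = signed_graph(edges),
       spec = generator_spec("two_cliques",
                             list(n1 = n1, n2 = n2,
                                  cliques = list(c1, c2)), seed, roles))
}

#' Five-club planted network
#'
#' Five cliques of random sizes between 16 and 20.  Three cliques get a
#' planted leader whose edges to every other member are drawn from
#' `[0.85, 1)`; two get a planted villain with edges in `(-1, -0.85]`.
#' Edges between ordinary members of a clique are drawn between 0.75 and the
#' lower of the two members' edge magnitudes to the clique's planted node.
#' A number of bridge nodes equal to half the largest clique size (rounded
#' up) each connect to one random ordinary member in each of two random
#' cliques with a weight in `[0.75, 1)`.
#'
#' @param seed integer RNG seed.
#' @param bridge_planted_ok allow bridges to attach to leaders/villains as
#'   well (default `FALSE` keeps the planted roles clean).
#' @return list with `graph` and `spec` (roles: `leader` x3, `villain` x2,
#'   `bridge`, `member`).
#' @export
five_club_network <- function(seed = 1, bridge_planted_ok = FALSE) {
  withr::with_seed(seed, {
    sizes <- sample(16:20, 5L, replace = TRUE)
    edges <- list()
    roles <- character(0)
    members_by_clique <- vector("list", 5L)
    for (k in seq_len(5L)) {
      is_leader <- k <= 3L
      planted <- sprintf("c%d%s", k, if (is_leader) "L" else "V")
      members <- sprintf("c%dm%02d", k, seq_len(sizes[k] - 1L))
      members_by_clique[[k]] <- members
      pw <- stats::runif(length(members), 0.85, 1)
      planted_w <- if (is_leader) pw else -pw
      edges[[length(edges) + 1L]] <-
        data.frame(from = planted, to = members, weight = planted_w)
      if (length(members) > 1L) {
        pairs <- utils::combn(seq_along(members), 2L)
        ub <- pmin(pw[pairs[1L, ]], pw[pairs[2L, ]])
        edges[[length(edges) + 1L]] <-
          data.frame(from = members[pairs[1L, ]],
                     to = members[pairs[2L, ]],
                     weight = stats::runif(ncol(pairs), 0.75, ub))
      }
      roles[planted] <- if (is_leader) "leader" else "villain"
      roles[members] <- "member"
    }
    n_bridge <- ceiling(max(sizes) / 2)
    planted_ids <- sprintf("c%d%s", 1:5, c("L", "L", "L", "V", "V"))
    # hosts are drawn without replacement across bridges: a member hosting
    # two bridge endpoints would itself act as a bridge, blurring the
    # planted roles the generator exists to test
    host_pools <- members_by_clique
    if (bridge_planted_ok)
      host_pools <- Map(c, host_pools, planted_ids)
    for (b in seq_len(n_bridge)) {
      id <- sprintf("br%02d", b)
      cliques <- sample(5L, 2L)
      targets <- vapply(cliques, function(k) {
        pool <- host_pools[[k]]
        pick <- pool[sample.int(length(pool), 1L)]
        host_pools[[k]] <<- setdiff(pool, pick)
        pick
      }, "")
      edges[[length(edges) + 1L]] <-
        data.frame(from = id, to = targets,
                   weight = stats::runif(2L, 0.75, 1))
      roles[id] <- "bridge"
    }
    g <- signed_graph(do.call(rbind, edges))
    list(graph = g,
         spec = generator_spec("five_club_network",
                               list(sizes = sizes, n_bridge = n_bridge,
                                    bridge_planted_ok = bridge_planted_ok),
                               seed, roles))
  })
}

#' Scale-free network with positive random weights
#'
#' Preferential attachment (`m` edges per arriving node) with i.i.d. uniform
#' (0,1) weights; the canonical model for hub-dominated biological networks
#' such as protein-protein interaction maps.
#'
#' @param n number of nodes.
#' @param m edges added per arriving node; must satisfy `m < n`.
#' @param seed integer RNG seed.
#' @return list with `graph` and `spec` (all roles `member`).
#' @export
scale_free <- function(n = 200, m = 2, seed = 1) {
  if (m >= n) stop("m must be smaller than n")
  if (n < 2L || m < 1L) stop("need n >= 2 and m >= 1")
  g <- withr::with_seed(seed, {
    sf <- igraph::sample_pa(n, m = m, directed = FALSE)
    igraph::V(sf)$name <- sprintf("v%04d", seq_len(n))
    igraph::E(sf)$weight <- stats::runif(igraph::ecount(sf))
    sf
  })
  roles <- stats::setNames(rep("member", n), igraph::V(g)$name)
  list(graph = validate_signed_graph(g),
       spec = generator_spec("scale_free", list(n = n, m = m), seed, roles))
}
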