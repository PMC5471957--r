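test_that("generators are pure functions of spec and seed", {
  gens <- list(
    function(s) clique_with_leader(5, seed = s)$graph,
    function(s) clique_with_villain(5, seed = s)$graph,
    function(s) rival_groups(c(3, 2), 0.7, seed = s)$graph,
    function(s) two_triads(seed = s)$graph,
    function(s) two_cliques(4, 6, seed = s)$graph,
    function(s) five_club_network(seed = s)$graph,
    function(s) scale_free(50, 2, seed = s)$graph)
  for (i in seq_along(gens)) {
    gen <- gens[[i]]
    a <- gen(7)
    b <- gen(7)
    expect_identical(igraph::as_data_frame(a), igraph::as_data_frame(b))
    expect_silent(validate_signed_graph(a))
    if (i != 3L)  # rival_groups is deterministic by construction
      expect_false(identical(igraph::as_data_frame(a),
                             igraph::as_data_frame(gen(8))))
  }
})

test_that("clique generators respect their weight-range contracts", {
  cl <- clique_with_leader(6, seed = 3)
  df <- igraph::as_data_frame(cl$graph)
  lw <- df$weight[df$from == "L" | df$to == "L"]
  mw <- df$weight[df$from != "L" & df$to != "L"]
  expect_true(all(lw >= 0.9 & lw <= 0.95))
  expect_true(all(mw >= 0.7 & mw <= 0.8))
  expect_error(clique_with_leader(4, leader_w = c(0.7, 0.9),
                                  member_w = c(0.6, 0.8)),
               "strictly above")
  expect_error(clique_with_leader(2), "at least 3")

  cv <- clique_with_villain(5, seed = 3)
  df <- igraph::as_data_frame(cv$graph)
  vw <- df$weight[df$from == "V" | df$to == "V"]
  expect_true(all(vw >= -0.95 & vw <= -0.9))
  expect_equal(sum(df$from == "V" | df$to == "V"), 5)
  expect_error(clique_with_villain(4, villain_w = c(-0.75, -0.7)),
               "stronger")
})

test_that("rival groups are uniform cliques with cross-group enmity", {
  rg <- rival_groups(c(2, 2), 0.8)
  df <- igraph::as_data_frame(rg$graph)
  expect_equal(nrow(df), 6)
  expect_setequal(unique(abs(df$weight)), 0.8)
  cross <- xor(grepl("^A", df$from), grepl("^A", df$to))
  expect_true(all(df$weight[cross] < 0))
  expect_true(all(df$weight[!cross] > 0))

  # single-pair case: one negative edge, symmetric pays
  pv <- pay_vector(rival_groups(c(1, 1), 0.6)$graph)
  expect_equal(unname(pv$pay), c(0.6, 0.6))
  # pays invariant under swapping the groups
  p1 <- pay_vector(rival_groups(c(3, 2), 0.7)$graph)$pay
  p2 <- pay_vector(rival_groups(c(2, 3), 0.7)$graph)$pay
  expect_equal(sort(unname(p1)), sort(unname(p2)), tolerance = 1e-12)
})

test_that("two-triad construction gives the leaders the strongest edges", {
  tt <- two_triads(seed = 9)
  df <- igraph::as_data_frame(tt$graph)
  w_of <- function(a, b) df$weight[(df$from == a & df$to == b) |
                                   (df$from == b & df$to == a)]
  expect_true(min(w_of("A", "B"), w_of("B", "C")) > w_of("A", "C"))
  expect_true(min(w_of("D", "E"), w_of("D", "F")) > w_of("E", "F"))
  expect_equal(w_of("C", "E"), 0.1)
  expect_error(two_triads(intra1 = c(0.7, 0.8), intra2 = c(0.75, 0.85)),
               "strictly above")
})

test_that("two disjoint cliques stay independent", {
  tc <- two_cliques(4, 5, seed = 2)
  g <- tc$graph
  expect_equal(igraph::vcount(g), 9)
  expect_equal(igraph::count_components(g), 2)
  # pays of one clique unchanged when the other is deleted
  pv <- pay_vector(g)
  sub <- igraph::induced_subgraph(g, tc$spec$params$cliques[[1]])
  pv_sub <- pay_vector(sub)
  expect_equal(pv$pay[names(pv_sub$pay)], pv_sub$pay, tolerance = 1e-12)
})

test_that("the five-club network follows its published construction", {
  for (s in c(1, 2)) {
    fc <- five_club_network(seed = s)
    g <- fc$graph
    roles <- fc$spec$roles
    sizes <- fc$spec$params$sizes
    expect_true(all(sizes >= 16 & sizes <= 20))
    n_bridge <- fc$spec$params$n_bridge
    expect_equal(n_bridge, ceiling(max(sizes) / 2))
    expect_equal(igraph::vcount(g), sum(sizes) + n_bridge)
    expect_true(igraph::vcount(g) >= 88 && igraph::vcount(g) <= 110)
    expect_equal(sum(roles == "leader"), 3)
    expect_equal(sum(roles == "villain"), 2)
    expect_equal(sum(roles == "bridge"), n_bridge)

    df <- igraph::as_data_frame(g)
    touches <- function(nodes) df$from %in% nodes | df$to %in% nodes
    leader_e <- df$weight[touches(names(roles)[roles == "leader"])]
    villain_e <- df$weight[touches(names(roles)[roles == "villain"])]
    expect_true(all(leader_e >= 0.85 & leader_e < 1))
    expect_true(all(villain_e > -1 & villain_e <= -0.85))
    bridge_ids <- names(roles)[roles == "bridge"]
    expect_true(all(igraph::degree(g, bridge_ids) == 2))
    bridge_e <- df$weight[touches(bridge_ids)]
    expect_true(all(bridge_e >= 0.75 & bridge_e < 1))
    member_e <- df$weight[!touches(c(bridge_ids,
                                     names(roles)[roles != "member"]))]
    expect_true(all(member_e >= 0.75 & member_e < 1))
    # bridges never land on planted nodes by default
    nb <- unlist(lapply(bridge_ids,
                        function(b) igraph::neighbors(g, b)$name))
    expect_true(all(roles[nb] == "member"))
  }
})

test_that("preferential attachment yields heavy-tailed degrees", {
  sf <- scale_free(200, 2, seed = 1)
  deg <- igraph::degree(sf$graph)
  expect_true(max(deg) >= 5 * stats::median(deg))
  expect_true(all(igraph::E(sf$graph)$weight > 0))
  expect_error(scale_free(5, 5), "smaller than n")
})
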