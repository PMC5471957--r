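test_that("the worked mixed-sign example yields the known gain and loss", {
  g <- worked_example_graph()
  gl <- gain_loss_from(g, "A")
  expect_equal(gl$gain[["D"]], -0.8 * 0.7 * -0.5, tolerance = 1e-15)
  expect_equal(gl$loss[["D"]], 0.2 * -0.5, tolerance = 1e-15)
  # two paths to C: direct 0.2 and A-B-C = -0.8*0.7 = -0.56
  expect_equal(gl$gain[["C"]], 0.2, tolerance = 1e-15)
  expect_equal(gl$loss[["C"]], -0.56, tolerance = 1e-12)
  expect_equal(gl$gain[["B"]], 0.2 * 0.7, tolerance = 1e-12)
  expect_equal(gl$loss[["B"]], -0.8, tolerance = 1e-15)
  # the source's own labels are excluded
  expect_identical(unname(gl$gain[["A"]]), 0)
  expect_identical(unname(gl$loss[["A"]]), 0)
})

test_that("single edges, unreachable nodes and edgeless graphs label as zero", {
  g <- signed_graph(data.frame(from = "A", to = "B", weight = 0.5),
                    nodes = "Z")
  gl <- gain_loss_from(g, "A")
  expect_equal(gl$gain[["B"]], 0.5)
  expect_identical(unname(gl$loss[["B"]]), 0)
  expect_identical(unname(gl$gain[["Z"]]), 0)
  expect_identical(unname(gl$loss[["Z"]]), 0)

  empty <- signed_graph(data.frame(from = character(), to = character(),
                                   weight = numeric()),
                        nodes = c("A", "B", "C"))
  pv <- pay_vector(empty)
  expect_true(all(pv$pay == 0))
})

test_that("engine matches the exhaustive simple-path oracle on mixed signs", {
  for (s in 1:20) {
    g <- random_signed_graph(sample(5:9, 1), 0.5, seed = s)
    if (igraph::ecount(g) == 0) next
    for (v in igraph::V(g)$name) {
      a <- gain_loss_from(g, v)
      b <- brute_force_gain_loss(g, v)
      expect_equal(a$gain, b$gain, tolerance = 1e-12)
      expect_equal(a$loss, b$loss, tolerance = 1e-12)
    }
  }
})

test_that("engine matches the oracle on balanced graphs (closed-form path)", {
  for (s in 1:10) {
    g <- random_balanced_graph(sample(5:9, 1), 0.5, seed = s)
    if (igraph::ecount(g) == 0) next
    for (v in igraph::V(g)$name) {
      a <- gain_loss_from(g, v)
      b <- brute_force_gain_loss(g, v)
      expect_equal(a$gain, b$gain, tolerance = 1e-12)
      expect_equal(a$loss, b$loss, tolerance = 1e-12)
    }
  }
})

test_that("gain/loss labels are symmetric on undirected graphs", {
  for (s in 1:5) {
    g <- random_signed_graph(7, 0.5, seed = s + 200)
    nm <- igraph::V(g)$name
    labels <- lapply(nm, function(v) gain_loss_from(g, v))
    names(labels) <- nm
    for (i in nm) for (j in nm) {
      expect_equal(labels[[i]]$gain[[j]], labels[[j]]$gain[[i]],
                   tolerance = 1e-12)
      expect_equal(labels[[i]]$loss[[j]], labels[[j]]$loss[[i]],
                   tolerance = 1e-12)
    }
  }
})

test_that("all-positive graphs have zero loss and max-product gains", {
  for (s in 1:5) {
    g <- random_signed_graph(8, 0.6, seed = s + 300)
    if (igraph::ecount(g) == 0) next
    igraph::E(g)$weight <- abs(igraph::E(g)$weight)
    for (v in igraph::V(g)$name) {
      gl <- gain_loss_from(g, v)
      expect_true(all(gl$loss == 0))
      expect_equal(gl$gain, brute_force_gain_loss(g, v)$gain,
                   tolerance = 1e-12)
    }
  }
})

test_that("label magnitudes stay within 1 and pay within n - 1", {
  for (s in 1:5) {
    g <- random_signed_graph(8, 0.7, seed = s + 400)
    pv <- pay_vector(g)
    expect_true(all(pv$pay <= igraph::vcount(g) - 1 + 1e-12))
    expect_equal(pv$pay, abs(pv$signed_pay))
    for (v in igraph::V(g)$name) {
      gl <- gain_loss_from(g, v)
      expect_true(all(gl$gain >= 0 & gl$gain <= 1))
      expect_true(all(gl$loss <= 0 & gl$loss >= -1))
    }
  }
})

test_that("uniform-weight graphs reduce to the delta^hops closed form", {
  # on a tree with all weights delta the unique path gives delta^hops
  set.seed(42)
  for (s in 1:5) {
    tree <- igraph::sample_tree(10)
    igraph::V(tree)$name <- sprintf("t%02d", 1:10)
    igraph::E(tree)$weight <- 0.5
    hops <- igraph::distances(tree, weights = NA)
    pv <- pay_vector(tree)
    expected <- rowSums(0.5^hops) - 1  # subtract the self term 0.5^0
    expect_equal(unname(pv$pay), unname(expected), tolerance = 1e-12)
  }
  # uniformly weighted clique: every node reaches the rest directly
  cl <- signed_graph(data.frame(t(utils::combn(LETTERS[1:5], 2)), 0.6))
  pv <- pay_vector(cl)
  expect_equal(unname(pv$pay), rep(4 * 0.6, 5), tolerance = 1e-12)
})

test_that("worked-example pay vector matches hand-enumerated sums", {
  pv <- pay_vector(worked_example_graph())
  # A: (0.14 - 0.8) + (0.2 - 0.56) + (0.28 - 0.1) = -0.84
  expect_equal(pv$signed_pay[["A"]], -0.84, tolerance = 1e-12)
  expect_equal(pv$pay[["A"]], 0.84, tolerance = 1e-12)
})

test_that("the brute-force oracle refuses oversized graphs", {
  g <- random_signed_graph(12, 0.4, seed = 9)
  expect_error(brute_force_gain_loss(g, "n01"), "capped")
  expect_silent(brute_force_gain_loss(g, "n01", max_nodes = 12))
})
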