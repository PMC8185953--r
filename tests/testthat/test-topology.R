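triangle <- function() {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- c("a", "b", "c")
  g
}

test_that("clustering factor matches the neighbour-pair definition", {
  expect_equal(unname(clustering_factor(triangle(), "a")), 1)

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "s1", "s2", "s3", "s4")
  expect_equal(unname(clustering_factor(star, "hub")), 0)
  # degree-1 leaves use the k < 2 convention
  expect_equal(unname(clustering_factor(star, "s1")), 0)

  # 5-node toy graph against brute-force enumeration
  el <- rbind(c("a", "b"), c("a", "c"), c("b", "c"), c("c", "d"),
              c("d", "e"), c("b", "d"))
  g <- as_ppi_graph(as.data.frame(el, stringsAsFactors = FALSE))
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  for (i in seq_along(igraph::V(g)$name)) {
    nm <- igraph::V(g)$name[i]
    expect_equal(unname(clustering_factor(g, nm)), oracle_clustering(A, i),
                 info = nm)
  }
  expect_error(clustering_factor(g, "zzz"), "not in the network")
})

test_that("topological coefficient counts shared neighbours with the direct-link credit", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  # shared = 2, +1 for the direct link, min degree 3 -> exactly 1
  expect_equal(topological_coefficient(k4, "a", "b"), 1)

  # bridge between two otherwise-disjoint triangles: no shared neighbours
  el <- rbind(c("a", "b"), c("a", "c"), c("b", "c"),
              c("d", "e"), c("d", "f"), c("e", "f"), c("c", "d"))
  g <- as_ppi_graph(as.data.frame(el, stringsAsFactors = FALSE))
  expect_equal(topological_coefficient(g, "c", "d"), (0 + 1) / 3)
  expect_equal(topological_coefficient(g, "a", "b"), (1 + 1) / 2)
  # symmetry and the not-an-edge error
  expect_equal(topological_coefficient(g, "d", "c"),
               topological_coefficient(g, "c", "d"))
  expect_error(topological_coefficient(g, "a", "f"), "not an edge")
})

test_that("PTC blends its components linearly in alpha and respects endpoints", {
  el <- rbind(c("a", "b"), c("a", "c"), c("b", "c"), c("c", "d"),
              c("b", "d"), c("d", "e"), c("a", "e"))
  g <- as_ppi_graph(as.data.frame(el, stringsAsFactors = FALSE))
  cc <- clustering_factor(g)
  for (e in list(c("a", "b"), c("c", "d"), c("d", "e"))) {
    cn <- (cc[[e[1]]] + cc[[e[2]]]) / 2
    tuv <- topological_coefficient(g, e[1], e[2])
    expect_equal(ptc(g, e[1], e[2], alpha = 1), cn)
    expect_equal(ptc(g, e[1], e[2], alpha = 0), tuv)
    expect_equal(ptc(g, e[1], e[2], alpha = 0.5), (cn + tuv) / 2)
    for (a in c(0.2, 0.37, 0.8))
      expect_equal(ptc(g, e[1], e[2], alpha = a), a * cn + (1 - a) * tuv)
  }
  # alternative endpoint-combination strategies
  expect_equal(ptc(g, "c", "d", alpha = 1, cn_combine = "min"),
               min(cc[["c"]], cc[["d"]]))
  expect_equal(ptc(g, "c", "d", alpha = 1, cn_combine = "max"),
               max(cc[["c"]], cc[["d"]]))
  expect_error(ptc(g, "a", "b", alpha = 1.2), "alpha")
})

test_that("PTC stays within [0, 1] across random graphs and the alpha grid", {
  for (s in 1:20) {
    rg <- random_graph(sample(6:25, 1), runif(1, 0.15, 0.6), seed = 300 + s)
    el <- igraph::as_edgelist(rg$g)
    if (nrow(el) == 0) next
    take <- head(seq_len(nrow(el)), 8)
    for (k in take) {
      for (a in c(0, 0.25, 0.5, 0.75, 1)) {
        val <- ptc(rg$g, el[k, 1], el[k, 2], alpha = a)
        expect_true(val >= 0 && val <= 1,
                    info = sprintf("seed %d edge %d alpha %g", s, k, a))
      }
    }
    # clustering factors also agree with the brute-force oracle
    cc <- clustering_factor(rg$g)
    for (i in seq_along(cc))
      expect_equal(unname(cc[i]), oracle_clustering(rg$A, i),
                   tolerance = 1e-12)
  }
})
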