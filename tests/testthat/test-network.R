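# a hand-checkable 4-node network: square with one diagonal, plus
# expression profiles engineered so (a, b) is perfectly correlated and
# (c, d) perfectly anti-correlated
toy_inputs <- function() {
  el <- data.frame(u = c("a", "b", "c", "d", "a"),
                   v = c("b", "c", "d", "a", "c"),
                   stringsAsFactors = FALSE)
  base <- c(1, 3, 2, 5, 4, 6)
  expr <- rbind(a = base, b = 2 * base + 1, c = base + c(0.5, -0.3, 0.2, 0.1, -0.4, 0),
                d = -(base + c(0.5, -0.3, 0.2, 0.1, -0.4, 0)))
  colnames(expr) <- paste0("t", 1:6)
  list(g = as_ppi_graph(el), expr = expr)
}

test_that("edge weights are the PTC x GEC product with the clamping policy", {
  ti <- toy_inputs()
  w <- build_weighted_network(ti$g, ti$expr, alpha = 0.8)
  e <- w$edges
  key <- paste(e$u, e$v)
  for (k in seq_len(nrow(e))) {
    expect_equal(e$ptc[k], ptc(ti$g, e$u[k], e$v[k], alpha = 0.8))
    expect_equal(e$gec_raw[k], jackknife_gec(ti$expr[e$u[k], ],
                                             ti$expr[e$v[k], ]))
    expect_equal(e$omega[k], e$ptc[k] * max(0, e$gec_raw[k]))
  }
  expect_equal(e$gec_raw[key == "a b"], 1)
  expect_gt(e$omega[key == "a b"], 0)
  # anti-correlated pair: raw GEC -1, clamped weight 0
  expect_equal(e$gec_raw[key == "c d"], -1)
  expect_equal(e$omega[key == "c d"], 0)
  # with clamping off the negative product survives
  w2 <- build_weighted_network(ti$g, ti$expr, alpha = 0.8, clamp_gec = FALSE)
  e2 <- w2$edges
  expect_lt(e2$omega[paste(e2$u, e2$v) == "c d"], 0)
})

test_that("node weights are the exact incident-edge sums and conserve total weight", {
  ti <- toy_inputs()
  w <- build_weighted_network(ti$g, ti$expr)
  for (nd in names(w$node_weight)) {
    inc <- w$edges$u == nd | w$edges$v == nd
    expect_equal(unname(w$node_weight[nd]), sum(w$edges$omega[inc]))
  }
  expect_equal(sum(w$node_weight), 2 * sum(w$edges$omega))

  # a larger random instance built through the full pipeline
  tr <- planted_truth(n_modules = 2, size_range = c(4, 5),
                      n_background = 15, seed = 5)
  w3 <- build_weighted_network(generate_network(tr), generate_expression(tr))
  expect_equal(sum(w3$node_weight), 2 * sum(w3$edges$omega))
  expect_true(all(w3$edges$omega >= 0 & w3$edges$omega <= 1))
})

test_that("missing-expression policies drop or zero the affected edges", {
  ti <- toy_inputs()
  expr_partial <- ti$expr[c("a", "b", "c"), ]
  wd <- build_weighted_network(ti$g, expr_partial, missing_policy = "drop")
  expect_false("d" %in% names(wd$node_weight))
  expect_equal(wd$report$edges_dropped_missing_expr, 2L)
  wz <- build_weighted_network(ti$g, expr_partial, missing_policy = "zero")
  ez <- wz$edges
  touched <- ez$u == "d" | ez$v == "d"
  expect_equal(nrow(ez), igraph::ecount(ti$g))
  expect_true(all(ez$omega[touched] == 0))
  expect_equal(wz$report$edges_defaulted_zero, 2L)
  # disjoint identifier namespaces signal a configuration problem
  rownames(expr_partial) <- c("x1", "x2", "x3")
  expect_error(build_weighted_network(ti$g, expr_partial), "no overlap")
})

test_that("network building is deterministic and node ranking is re-sum-consistent", {
  tr <- planted_truth(n_modules = 2, size_range = c(4, 6),
                      n_background = 12, seed = 9)
  g <- generate_network(tr); expr <- generate_expression(tr)
  w1 <- build_weighted_network(g, expr)
  w2 <- build_weighted_network(g, expr)
  expect_identical(w1$edges, w2$edges)
  expect_identical(w1$node_weight, w2$node_weight)

  r <- rank_nodes_by_weight(w1)
  resum <- vapply(r, function(nd)
    sum(w1$edges$omega[w1$edges$u == nd | w1$edges$v == nd]), numeric(1))
  expect_true(all(diff(resum) <= 1e-12))

  # dominance: a hub carrying all heavy edges ranks first, and exact ties
  # break lexicographically
  wh <- as_weighted_ppi(data.frame(u = c("hub", "hub", "hub", "x"),
                                   v = c("x", "y", "z", "y"),
                                   omega = c(0.9, 0.8, 0.7, 0.05)))
  expect_equal(rank_nodes_by_weight(wh)[1], "hub")
  wt <- as_weighted_ppi(data.frame(u = c("b", "a"), v = c("c", "d"),
                                   omega = c(0.5, 0.5)))
  expect_equal(rank_nodes_by_weight(wt), c("a", "b", "c", "d"))
})
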