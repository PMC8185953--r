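test_that("seed selection picks the heaviest free edge with deterministic ties", {
  w <- as_weighted_ppi(data.frame(u = c("a", "b", "c", "e"),
                                  v = c("b", "c", "d", "f"),
                                  omega = c(0.4, 0.9, 0.6, 0.9)))
  s <- select_seed_edge(w)
  # tie at 0.9 between (b, c) and (e, f): lexicographic endpoint order wins
  expect_equal(c(s$u, s$v), c("b", "c"))
  s2 <- select_seed_edge(w, consumed = c("b", "c"))
  expect_equal(c(s2$u, s2$v), c("e", "f"))
  # both endpoints must be unconsumed
  s3 <- select_seed_edge(w, consumed = c("b", "f"))
  expect_equal(c(s3$u, s3$v), c("c", "d"))
  expect_null(select_seed_edge(w, consumed = c("a", "b", "c", "d", "e", "f")))
})

test_that("gated expansion follows the threshold rule on a hand-traced path", {
  expect_equal(expand_seed(path_weighted(0.9, 0.9, 0.9),
                           list(u = "a", v = "b"), 0.7),
               c("a", "b", "c", "d"))
  expect_equal(expand_seed(path_weighted(0.9, 0.9, 0.5),
                           list(u = "a", v = "b"), 0.7),
               c("a", "b", "c"))
  # nothing passes a gate above every weight
  expect_equal(expand_seed(path_weighted(0.6, 0.6, 0.6),
                           list(u = "a", v = "b"), 0.95),
               c("a", "b"))
  expect_error(expand_seed(path_weighted(), list(u = "a", v = "b"), 1.5),
               "lambda")
  # the gate is inclusive: weight exactly at lambda absorbs
  expect_equal(expand_seed(path_weighted(0.9, 0.7, 0.9),
                           list(u = "a", v = "b"), 0.7),
               c("a", "b", "c", "d"))
})

test_that("overlap score is the maximum Jaccard against the collection", {
  e <- c("a", "b", "c")
  expect_equal(overlap_score(e, list()), 0)
  expect_equal(overlap_score(e, list(c("a", "b", "c"))), 1)
  expect_equal(overlap_score(e, list(c("x", "y"))), 0)
  expect_equal(overlap_score(e, list(c("b", "c", "d"))), 0.5)
  expect_equal(overlap_score(e, list(c("x", "y"), c("b", "c", "d"),
                                     c("a", "q", "r", "s"))), 0.5)
})

test_that("the detector recovers disjoint cliques and applies both filters", {
  tri2 <- as_weighted_ppi(data.frame(
    u = c("a", "a", "b", "x", "x", "y"),
    v = c("b", "c", "c", "y", "z", "z"),
    omega = rep(0.9, 6)))
  mods <- detect_modules(tri2, lambda = 0.7, ov_max = 0.8, min_size = 3)
  expect_length(mods, 2)
  expect_equal(sort(vapply(module_members(mods), paste, character(1),
                           collapse = "")), c("abc", "xyz"))
  # seed endpoints always belong to their module
  for (m in unclass(mods))
    expect_true(all(c(m$seed$u, m$seed$v) %in% m$members))

  # a single heavy edge with no qualifying neighbour dies at the size filter
  lone <- as_weighted_ppi(data.frame(u = c("a", "b"), v = c("b", "c"),
                                     omega = c(0.9, 0.3)))
  expect_length(detect_modules(lone, lambda = 0.7), 0)

  # expansion runs to closure, so detected modules are the connected
  # components of the lambda-thresholded subgraph: pairwise disjoint
  mem <- module_members(mods)
  expect_equal(length(intersect(mem[[1]], mem[[2]])), 0)
})

test_that("the maximum-overlap filter drops later near-duplicates, strictly", {
  a <- c("a", "b", "c"); a2 <- c("a", "b", "c")
  b <- c("b", "c", "d"); z <- c("x", "y", "z")
  # identical member sets: Jaccard 1 > 0.9, second one excluded
  expect_equal(filter_modules_by_overlap(list(a, a2, z), 0.9), list(a, z))
  # Jaccard({a,b,c},{b,c,d}) = 0.5: kept at 0.5 (strict >), dropped at 0.49
  expect_equal(filter_modules_by_overlap(list(a, b), 0.5), list(a, b))
  expect_equal(filter_modules_by_overlap(list(a, b), 0.49), list(a))
  # creation order wins: the earlier module is never revisited
  expect_equal(filter_modules_by_overlap(list(b, a, z), 0.49), list(b, z))
  expect_error(filter_modules_by_overlap(list(a), 0), "ov_max")
})

test_that("expansion agrees with the exhaustive fixpoint oracle and shrinks with lambda", {
  for (s in 1:60) {
    w <- random_weighted(sample(5:12, 1), runif(1, 0.25, 0.7), seed = 900 + s)
    if (is.null(w)) next
    e <- w$edges
    for (k in seq_len(min(nrow(e), 6))) {
      lam <- runif(1, 0.05, 0.95)
      got <- expand_seed(w, list(u = e$u[k], v = e$v[k]), lam)
      expect_equal(got, oracle_expand(e, e$u[k], e$v[k], lam),
                   info = sprintf("seed %d edge %d lam %.3f", s, k, lam))
      # monotonicity: a lower gate absorbs a superset
      lam2 <- lam * 0.5
      expect_true(all(got %in% expand_seed(w, list(u = e$u[k], v = e$v[k]),
                                           lam2)))
      # fixed point: re-running the absorption rule on the result adds nothing
      expect_equal(oracle_expand(e[e$u %in% got & e$v %in% got, ,
                                   drop = FALSE],
                                 e$u[k], e$v[k], lam), got)
    }
  }
})

test_that("retained modules satisfy the size and pairwise-overlap contracts deterministically", {
  for (s in 1:25) {
    w <- random_weighted(sample(8:20, 1), runif(1, 0.2, 0.5), seed = 1700 + s)
    if (is.null(w)) next
    lam <- runif(1, 0.2, 0.8)
    ovm <- runif(1, 0.3, 0.9)
    mods <- detect_modules(w, lambda = lam, ov_max = ovm)
    mem <- module_members(mods)
    expect_true(all(lengths(mem) >= 3))
    if (length(mem) > 1) {
      for (i in 2:length(mem))
        expect_lte(overlap_score(mem[[i]], mem[seq_len(i - 1)]), ovm)
    }
    expect_identical(mods, detect_modules(w, lambda = lam, ov_max = ovm))
    # strict mode forces pairwise-disjoint modules
    strict <- module_members(detect_modules(w, lambda = lam, ov_max = ovm,
                                            mode = "strict"))
    if (length(strict) > 1)
      expect_equal(anyDuplicated(unlist(strict)), 0)
  }
})
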