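test_that("matching score follows the neighbourhood-affinity definition", {
  s <- c("a", "b", "c")
  expect_equal(matching_score(s, s), 1)
  expect_equal(matching_score(s, c("x", "y")), 0)
  expect_equal(matching_score(c("a", "b", "c", "d"), c("c", "d", "e")),
               4 / 12)
  expect_equal(matching_score(s, c("b", "c", "d"), method = "jaccard"), 0.5)
  expect_equal(matching_score(s, c("x", "a")), matching_score(c("x", "a"), s))
  expect_error(matching_score(character(0), s), "nonempty")
})

test_that("F-measure is the harmonic mean with the zero convention", {
  expect_equal(f_measure(0, 0), 0)
  expect_equal(f_measure(1, 1), 1)
  set.seed(3)
  p <- runif(50); r <- runif(50)
  f <- f_measure(p, r)
  expect_true(all(f >= pmin(p, r) - 1e-12 & f <= pmax(p, r) + 1e-12))
})

test_that("precision, recall and coverage behave on constructed catalogs", {
  refs <- list(c("a", "b", "c"), c("d", "e", "f", "g"), c("h", "i", "j"))
  # exact detection
  ev <- evaluate_modules(refs, refs, match_threshold = 0.9)
  expect_equal(ev$precision, 1); expect_equal(ev$recall, 1)
  expect_equal(ev$fmeasure, 1); expect_equal(ev$coverage, 1)

  preds <- list(c("a", "b", "x"), c("q", "r", "s"))
  ev2 <- evaluate_modules(preds, refs, match_threshold = 0.2)
  # module 1 hits complex 1 with affinity 4/9 >= 0.2; module 2 hits nothing
  expect_equal(ev2$precision, 0.5)
  expect_equal(ev2$recall, 1 / 3)
  expect_equal(ev2$fmeasure, f_measure(0.5, 1 / 3))
  expect_equal(ev2$coverage, 2 / 10)  # a, b of the 10 benchmark proteins

  # raising the threshold never increases precision or recall
  prev_p <- 1; prev_r <- 1
  for (t in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    e <- evaluate_modules(preds, refs, match_threshold = t)
    expect_lte(e$precision, prev_p); expect_lte(e$recall, prev_r)
    prev_p <- e$precision; prev_r <- e$recall
  }
  expect_equal(coverage_rate(list(), refs), 0)
})

test_that("hypergeometric tail matches closed forms, an independent oracle, and enumeration", {
  expect_equal(hypergeom_pvalue(10, 5, 5, 5), 1 / choose(10, 5))
  expect_identical(hypergeom_pvalue(50, 10, 8, 0), 1)
  expect_error(hypergeom_pvalue(10, 11, 5, 2), "M <= N")
  expect_error(hypergeom_pvalue(10, 5, 5, 6), "exceed")

  # independent survival-function oracle on random queries
  set.seed(77)
  for (i in 1:200) {
    N <- sample(5:400, 1)
    M <- sample(0:N, 1)
    n <- sample(1:N, 1)
    x <- sample(0:min(M, n), 1)
    p <- hypergeom_pvalue(N, M, n, x)
    ref <- stats::phyper(x - 1, M, N - M, n, lower.tail = FALSE)
    expect_equal(p, ref, tolerance = 1e-12,
                 info = sprintf("N=%d M=%d n=%d x=%d", N, M, n, x))
  }

  # exhaustive draw enumeration for small backgrounds
  for (N in c(5, 8, 12)) {
    for (M in c(0, 2, N %/% 2, N)) {
      for (n in c(1, N %/% 2, N - 1)) {
        for (x in 0:min(M, n)) {
          expect_equal(hypergeom_pvalue(N, M, n, x),
                       oracle_hyper_enum(N, M, n, x), tolerance = 1e-12,
                       info = sprintf("N=%d M=%d n=%d x=%d", N, M, n, x))
        }
      }
    }
  }

  # non-increasing in x at fixed (N, M, n)
  ps <- vapply(0:12, function(x) hypergeom_pvalue(60, 20, 12, x), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))

  # log-space path stays finite and positive at extreme-tail scale
  p_deep <- hypergeom_pvalue(4616, 30, 25, 25)
  expect_true(is.finite(p_deep) && p_deep > 0)
  expect_lt(log10(p_deep), -30)
})

test_that("enrichment summary scores best-per-module P with strict thresholds", {
  # one module, one term covering exactly its members in a 10-protein world
  ann <- list(T1 = sprintf("g%02d", 1:5), T2 = sprintf("g%02d", 6:10))
  mod <- list(sprintf("g%02d", 1:5))
  en <- enrichment_summary(mod, ann, thresholds = c(1e-2, 1))
  expect_equal(en$per_module$best_p, 1 / choose(10, 5))
  expect_equal(en$per_module$best_term, "T1")
  expect_equal(en$avg_neglog10_p, -log10(1 / 252), tolerance = 1e-10)
  expect_equal(unname(en$percent_below), c(100, 100))

  # strict '<': a module whose best P is exactly 1 never counts, even at 1.0
  mods <- list(sprintf("g%02d", 1:5), c("zz1", "zz2", "zz3"))
  expect_message(en2 <- enrichment_summary(mods, ann, thresholds = 1),
                 "no annotated members")
  expect_equal(unname(en2$percent_below), 50)
  expect_equal(en2$n_unannotated, 1)

  # every module sharing a covering term is significant at loose thresholds
  truth <- planted_truth(n_modules = 3, size_range = c(5, 6),
                         n_background = 30, seed = 21)
  en3 <- enrichment_summary(truth_as_catalog(truth),
                            truth_as_annotations(truth),
                            thresholds = c(1e-5, 1e-2))
  expect_true(all(en3$per_module$best_p < 1e-5))
  expect_equal(unname(en3$percent_below), c(100, 100))
})
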