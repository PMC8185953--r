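# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (element-wise loops, exhaustive scans) so they check
# the package's optimised paths from a different direction.

oracle_pearson <- function(u, v) {
  n <- length(u)
  mu <- sum(u) / n
  mv <- sum(v) / n
  num <- 0; du <- 0; dv <- 0
  for (j in seq_len(n)) {
    num <- num + (u[j] - mu) * (v[j] - mv)
    du <- du + (u[j] - mu)^2
    dv <- dv + (v[j] - mv)^2
  }
  if (du == 0 || dv == 0) return(0)
  num / sqrt(du * dv)
}

oracle_jackknife <- function(u, v) {
  min(vapply(seq_along(u), function(j) oracle_pearson(u[-j], v[-j]),
             numeric(1)))
}

oracle_euclidean <- function(u, v) {
  s <- 0
  for (j in seq_along(u)) s <- s + (u[j] - v[j])^2
  sqrt(s)
}

oracle_cosine <- function(u, v) {
  sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
}

# clustering coefficient by explicit neighbour-pair enumeration on an
# adjacency matrix
oracle_clustering <- function(A, i) {
  nb <- which(A[i, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  cnt <- 0
  for (a in seq_len(k - 1))
    for (b in (a + 1):k)
      if (A[nb[a], nb[b]] > 0) cnt <- cnt + 1
  2 * cnt / (k * (k - 1))
}

# absorption-rule fixpoint by exhaustive rescanning: grow the member set
# until no node anywhere in the graph is adjacent to a member through an
# edge of weight >= lambda
oracle_expand <- function(edges, seed_u, seed_v, lambda) {
  members <- c(seed_u, seed_v)
  repeat {
    added <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$u[k]; b <- edges$v[k]; w <- edges$omega[k]
      if (w >= lambda) {
        if (a %in% members && !(b %in% members)) {
          members <- c(members, b); added <- TRUE
        } else if (b %in% members && !(a %in% members)) {
          members <- c(members, a); added <- TRUE
        }
      }
    }
    if (!added) break
  }
  sort(unique(members))
}

# hypergeometric tail by exhaustive enumeration of all C(N, n) draws
oracle_hyper_enum <- function(N, M, n, x) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= M)  # proteins 1..M carry the term
  mean(hits >= x)
}

# random Erdos-Renyi-style graph as a named igraph
random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  list(g = g, A = A)
}

# random weighted network (uniform weights in [0, 1])
random_weighted <- function(n, p, seed) {
  rg <- random_graph(n, p, seed)
  el <- igraph::as_edgelist(rg$g)
  if (nrow(el) == 0) return(NULL)
  set.seed(seed + 1)
  as_weighted_ppi(data.frame(u = el[, 1], v = el[, 2],
                             omega = runif(nrow(el)),
                             stringsAsFactors = FALSE))
}

# tiny hand-built weighted path a-b-c-d
path_weighted <- function(w_ab = 0.9, w_bc = 0.9, w_cd = 0.9) {
  as_weighted_ppi(data.frame(u = c("a", "b", "c"), v = c("b", "c", "d"),
                             omega = c(w_ab, w_bc, w_cd),
                             stringsAsFactors = FALSE))
}
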