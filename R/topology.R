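## Topological feature extraction on the PPI graph.
##
## Three quantities feed edge re-weighting:
##   * the clustering factor Cn(u): the local clustering coefficient, i.e.
##     the fraction of u's neighbour pairs that interact with each other;
##   * the topological coefficient T(u,v): a shared-neighbour score in the
##     mutual-clustering-coefficient lineage, (|N(u) n N(v)| + 1) /
##     min(deg u, deg v), capped at 1 (the +1 credits the direct link);
##   * PTC(u,v) = alpha * Cn + (1 - alpha) * T(u,v), the blend the detector
##     uses, where the per-edge Cn combines the endpoint coefficients
##     (mean by default; min and max are available strategies).

#' Coerce input to an undirected simple PPI graph
#'
#' Accepts an igraph object, a two-column matrix/data frame of endpoint
#' identifiers, or a path to an edge-list TSV (see [read_ppi_edges()]).
#' Direction, self-loops and duplicate edges are removed.
#'
#' @param x Graph-like input.
#' @return An undirected simple `igraph` with a `name` vertex attribute.
#' @export
as_ppi_graph <- function(x) {
  if (igraph::is_igraph(x)) {
    g <- x
    if (is.null(igraph::V(g)$name))
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  } else if (is.character(x) && length(x) == 1) {
    return(read_ppi_edges(x))
  } else if (is.matrix(x) || is.data.frame(x)) {
    if (ncol(x) < 2)
      stop("edge input needs two identifier columns", call. = FALSE)
    el <- cbind(as.character(x[[1]]), as.character(x[[2]]))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
  } else {
    stop("cannot interpret input as a PPI graph", call. = FALSE)
  }
  g <- igraph::as_undirected(g, mode = "collapse")
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

.check_vertex <- function(g, u) {
  if (!u %in% igraph::V(g)$name)
    stop(sprintf("node '%s' is not in the network", u), call. = FALSE)
  invisible(TRUE)
}

#' Local clustering factor of network nodes
#'
#' Fraction of a node's neighbour pairs that are themselves connected,
#' `2 * e_N / (k * (k - 1))` with `k` the degree and `e_N` the edge count
#' among the neighbours. Nodes of degree < 2 score 0 (standard convention,
#' avoiding 0/0).
#'
#' @param g A PPI graph ([as_ppi_graph()]).
#' @param v Optional character vector of node names; default all nodes.
#' @return Named numeric vector in \[0, 1\].
#' @export
clustering_factor <- function(g, v = NULL) {
  g <- as_ppi_graph(g)
  if (is.null(v)) v <- igraph::V(g)$name
  for (u in v) .check_vertex(g, u)
  cc <- igraph::transitivity(g, type = "local", vids = v, isolates = "zero")
  setNames(cc, v)
}

#' Topological coefficient of an interacting pair
#'
#' Shared-neighbour score `min(1, (|N(u) n N(v)| + 1) / min(k_u, k_v))` for
#' an edge (u, v); the +1 accounts for the endpoints being directly linked,
#' so the score is strictly positive on every edge and 1 when the sparser
#' endpoint's neighbourhood (besides v itself) lies entirely in the
#' intersection.
#'
#' @param g A PPI graph.
#' @param u,v Names of two adjacent nodes.
#' @return Scalar in (0, 1\].
#' @export
topological_coefficient <- function(g, u, v) {
  g <- as_ppi_graph(g)
  .check_vertex(g, u); .check_vertex(g, v)
  if (!igraph::are_adjacent(g, u, v))
    stop(sprintf("(%s, %s) is not an edge of the network", u, v),
         call. = FALSE)
  nu <- igraph::neighbors(g, u)$name
  nv <- igraph::neighbors(g, v)$name
  shared <- length(intersect(nu, nv))
  min(1, (shared + 1) / min(length(nu), length(nv)))
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

.combine_cn <- function(cu, cv, cn_combine) {
  switch(cn_combine,
         mean = (cu + cv) / 2,
         min  = pmin(cu, cv),
         max  = pmax(cu, cv),
         stop("unknown cn_combine strategy", call. = FALSE))
}

#' Pairwise topological coefficient PTC of an edge
#'
#' `PTC(u, v) = alpha * Cn(u, v) + (1 - alpha) * T(u, v)` where
#' `Cn(u, v)` combines the endpoints' clustering factors (strategy
#' `cn_combine`, mean by default) and `T(u, v)` is the shared-neighbour
#' coefficient. Lies in \[0, 1\] and is linear in `alpha`.
#'
#' @inheritParams topological_coefficient
#' @param alpha Blend weight on the clustering-factor term, in \[0, 1\]
#'   (default 0.8).
#' @param cn_combine How the two endpoint clustering factors form the
#'   per-edge term: `"mean"` (default), `"min"` or `"max"`.
#' @return Scalar in \[0, 1\].
#' @export
ptc <- function(g, u, v, alpha = 0.8, cn_combine = c("mean", "min", "max")) {
  cn_combine <- match.arg(cn_combine)
  .check_alpha(alpha)
  g <- as_ppi_graph(g)
  cc <- clustering_factor(g, c(u, v))
  tuv <- topological_coefficient(g, u, v)
  alpha * .combine_cn(cc[[1]], cc[[2]], cn_combine) + (1 - alpha) * tuv
}

# Vectorised PTC over every edge of g; returns a data.frame
# (u, v, cn, tuv, ptc) with u < v lexicographically. Used by the
# network-reconstruction step to avoid per-edge graph queries.
edge_ptc_table <- function(g, alpha = 0.8,
                           cn_combine = c("mean", "min", "max")) {
  cn_combine <- match.arg(cn_combine)
  .check_alpha(alpha)
  g <- as_ppi_graph(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  nm <- igraph::V(g)$name
  if (nrow(el) == 0)
    return(data.frame(u = character(), v = character(), cn = numeric(),
                      tuv = numeric(), ptc = numeric(),
                      stringsAsFactors = FALSE))
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  shared <- vapply(seq_len(nrow(el)), function(k) {
    length(intersect(as.integer(adj[[el[k, 1]]]),
                     as.integer(adj[[el[k, 2]]])))
  }, integer(1))
  tuv <- pmin(1, (shared + 1) / pmin(deg[el[, 1]], deg[el[, 2]]))
  cn <- .combine_cn(cc[el[, 1]], cc[el[, 2]], cn_combine)
  u <- nm[el[, 1]]; v <- nm[el[, 2]]
  swap <- u > v
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  out <- data.frame(u = u, v = v, cn = cn, tuv = unname(tuv),
                    ptc = alpha * cn + (1 - alpha) * unname(tuv),
                    stringsAsFactors = FALSE)
  out[order(out$u, out$v), , drop = FALSE]
}
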