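## Network reconstruction: fuse topology (PTC) and coexpression (GEC) into
## edge weights omega(u,v) = PTC(u,v) * GEC(u,v) and node weights
## omega(u) = sum of incident edge weights. The weighted graph is what the
## seed-expansion detector consumes.

#' Build the topology- and coexpression-weighted PPI network
#'
#' Every edge (u, v) of the input graph whose endpoints both have expression
#' profiles receives the weight `omega(u, v) = PTC(u, v) * GEC(u, v)`;
#' each node then carries `omega(u)`, the sum of its incident edge weights.
#'
#' Negative GEC means anti-correlated expression; since the expansion gate
#' only ever admits weights above a positive threshold, negative values are
#' clamped to 0 for weighting by default (`clamp_gec = TRUE`) and the raw
#' value is kept in the per-edge trace. Edges with an unmeasured endpoint
#' are removed (`missing_policy = "drop"`) or kept with GEC 0
#' (`missing_policy = "zero"`).
#'
#' @param g PPI graph input ([as_ppi_graph()]).
#' @param expr Numeric expression matrix, rownames = gene/protein ids,
#'   >= 4 columns (conditions), or a path readable by
#'   [read_expression_matrix()].
#' @param alpha Blend weight of the clustering factor in PTC (default 0.8).
#' @param cn_combine Endpoint clustering-factor combination strategy.
#' @param missing_policy `"drop"` (default) or `"zero"`; see Details.
#' @param clamp_gec Clamp negative GEC to 0 for weighting (default TRUE).
#' @param similarity Which expression similarity feeds the weight:
#'   `"jackknife"` (default; the GEC), `"pearson"` or `"cosine"`.
#' @return A `weighted_ppi` object: list with `graph` (igraph with edge
#'   attributes `omega`, `ptc`, `gec_raw`, `gec_used`), `edges` (data frame
#'   u, v, omega, ptc, gec_raw, gec_used with u < v), `node_weight` (named
#'   vector) and `report` (build counts).
#' @export
build_weighted_network <- function(g, expr, alpha = 0.8,
                                   cn_combine = c("mean", "min", "max"),
                                   missing_policy = c("drop", "zero"),
                                   clamp_gec = TRUE,
                                   similarity = c("jackknife", "pearson",
                                                  "cosine")) {
  cn_combine <- match.arg(cn_combine)
  missing_policy <- match.arg(missing_policy)
  similarity <- match.arg(similarity)
  .check_alpha(alpha)
  g <- as_ppi_graph(g)
  if (is.character(expr) && length(expr) == 1)
    expr <- read_expression_matrix(expr)
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop("expr must be a numeric matrix with gene rownames", call. = FALSE)
  if (igraph::vcount(g) == 0 || igraph::ecount(g) == 0)
    stop("PPI network has no edges to weight", call. = FALSE)
  if (similarity == "jackknife" && ncol(expr) < 4)
    stop("Jackknife GEC needs >= 4 conditions", call. = FALSE)
  measured <- intersect(igraph::V(g)$name, rownames(expr))
  if (length(measured) == 0)
    stop(paste("no overlap between network proteins and expression genes -",
               "check that the two files use the same identifier namespace"),
         call. = FALSE)

  n_nodes0 <- igraph::vcount(g)
  n_edges0 <- igraph::ecount(g)
  simfun <- switch(similarity,
                   jackknife = jackknife_gec,
                   pearson = pearson_cor,
                   cosine = cosine_similarity)

  # PTC is computed on the full input topology before any expression-driven
  # edge removal, so a missing profile does not alter its neighbours' scores
  tab <- edge_ptc_table(g, alpha = alpha, cn_combine = cn_combine)
  has_expr_u <- tab$u %in% measured
  has_expr_v <- tab$v %in% measured
  covered <- has_expr_u & has_expr_v
  gec_raw <- rep(NA_real_, nrow(tab))
  if (any(covered)) {
    gec_raw[covered] <- vapply(which(covered), function(k)
      simfun(expr[tab$u[k], ], expr[tab$v[k], ]), numeric(1))
  }
  if (missing_policy == "drop") {
    dropped <- sum(!covered)
    tab <- tab[covered, , drop = FALSE]
    gec_raw <- gec_raw[covered]
    defaulted <- 0L
  } else {
    dropped <- 0L
    defaulted <- sum(!covered)
    gec_raw[!covered] <- 0
  }
  if (nrow(tab) == 0)
    stop("no edges survive the missing-expression policy", call. = FALSE)
  gec_used <- if (clamp_gec) pmax(gec_raw, 0) else gec_raw
  omega <- tab$ptc * gec_used

  wg <- igraph::graph_from_data_frame(
    data.frame(from = tab$u, to = tab$v, omega = omega, ptc = tab$ptc,
               gec_raw = gec_raw, gec_used = gec_used,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sort(unique(c(tab$u, tab$v))),
                          stringsAsFactors = FALSE))
  node_w <- igraph::strength(wg, weights = igraph::E(wg)$omega)
  igraph::V(wg)$weight <- node_w

  edges <- data.frame(u = tab$u, v = tab$v, omega = omega, ptc = tab$ptc,
                      gec_raw = gec_raw, gec_used = gec_used,
                      stringsAsFactors = FALSE)
  structure(list(
    graph = wg,
    edges = edges,
    node_weight = setNames(as.numeric(node_w), igraph::V(wg)$name),
    params = list(alpha = alpha, cn_combine = cn_combine,
                  missing_policy = missing_policy, clamp_gec = clamp_gec,
                  similarity = similarity),
    report = list(nodes_in = n_nodes0, edges_in = n_edges0,
                  nodes_out = igraph::vcount(wg),
                  edges_out = nrow(edges),
                  nodes_measured = length(measured),
                  edges_dropped_missing_expr = as.integer(dropped),
                  edges_defaulted_zero = as.integer(defaulted))),
    class = "weighted_ppi")
}

#' @export
print.weighted_ppi <- function(x, ...) {
  r <- x$report
  cat("Weighted PPI network\n")
  cat(sprintf("  input:  %d nodes, %d edges (%d with expression)\n",
              r$nodes_in, r$edges_in, r$nodes_measured))
  cat(sprintf("  output: %d nodes, %d weighted edges (%d dropped, %d zeroed)\n",
              r$nodes_out, r$edges_out, r$edges_dropped_missing_expr,
              r$edges_defaulted_zero))
  cat(sprintf("  omega: mean %.3f, max %.3f | alpha = %g, similarity = %s\n",
              mean(x$edges$omega), max(x$edges$omega), x$params$alpha,
              x$params$similarity))
  invisible(x)
}

#' Node weights of a weighted PPI network
#'
#' @param w A `weighted_ppi` object.
#' @return Named numeric vector: `omega(u)` per node.
#' @export
node_weights <- function(w) {
  stopifnot(inherits(w, "weighted_ppi"))
  w$node_weight
}

#' Rank nodes by weight
#'
#' Nodes sorted by `omega(u)` descending; ties broken lexicographically by
#' identifier so the ranking is deterministic.
#'
#' @param w A `weighted_ppi` object.
#' @return Character vector of node names, heaviest first.
#' @export
rank_nodes_by_weight <- function(w) {
  nw <- node_weights(w)
  names(nw)[order(-nw, names(nw), method = "radix")]
}

#' Construct a weighted PPI network from an edge table
#'
#' Builds a `weighted_ppi` object directly from per-edge weights, e.g. a
#' network weighted by an external procedure or a hand-specified test
#' graph. Reversed duplicates are collapsed (keeping the first weight);
#' self-loops are rejected.
#'
#' @param edges Data frame with columns `u`, `v`, `omega` (and optionally
#'   `ptc`, `gec_raw`, `gec_used`).
#' @return A `weighted_ppi` object.
#' @export
as_weighted_ppi <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("u", "v", "omega") %in% names(edges)))
    stop("edges needs columns u, v, omega", call. = FALSE)
  u <- as.character(edges$u); v <- as.character(edges$v)
  if (any(u == v)) stop("self-loops are not allowed", call. = FALSE)
  swap <- u > v
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  key <- paste(u, v, sep = "\r")
  keep <- !duplicated(key)
  tab <- data.frame(u = u[keep], v = v[keep],
                    omega = as.numeric(edges$omega)[keep],
                    ptc = if ("ptc" %in% names(edges))
                      as.numeric(edges$ptc)[keep] else NA_real_,
                    gec_raw = if ("gec_raw" %in% names(edges))
                      as.numeric(edges$gec_raw)[keep] else NA_real_,
                    gec_used = if ("gec_used" %in% names(edges))
                      as.numeric(edges$gec_used)[keep] else NA_real_,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$u, tab$v), , drop = FALSE]
  rownames(tab) <- NULL
  wg <- igraph::graph_from_data_frame(
    data.frame(from = tab$u, to = tab$v, omega = tab$omega,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sort(unique(c(tab$u, tab$v))),
                          stringsAsFactors = FALSE))
  node_w <- igraph::strength(wg, weights = igraph::E(wg)$omega)
  igraph::V(wg)$weight <- node_w
  structure(list(graph = wg, edges = tab,
                 node_weight = setNames(as.numeric(node_w),
                                        igraph::V(wg)$name),
                 params = list(alpha = NA_real_, cn_combine = NA_character_,
                               missing_policy = NA_character_,
                               clamp_gec = NA, similarity = "external"),
                 report = list(nodes_in = igraph::vcount(wg),
                               edges_in = nrow(tab),
                               nodes_out = igraph::vcount(wg),
                               edges_out = nrow(tab),
                               nodes_measured = igraph::vcount(wg),
                               edges_dropped_missing_expr = 0L,
                               edges_defaulted_zero = 0L)),
            class = "weighted_ppi")
}
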