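#' Detect protein functional modules from a PPI network and expression data
#'
#' The main fitting function. The interaction network is re-weighted edge
#' by edge with `omega(u, v) = PTC(u, v) * GEC(u, v)`, the product of a
#' topological coefficient — an `alpha`-blend of the endpoints' local
#' clustering factors with a shared-neighbour coefficient — and the
#' Jackknife coexpression correlation of the two genes' expression
#' profiles. Modules are then grown greedily: the heaviest edge whose
#' endpoints are still unused seeds a complex, which absorbs, breadth
#' first, every neighbour connected by an edge of weight at least
#' `lambda`; finally modules smaller than `min_size` and modules whose
#' Jaccard overlap with an earlier module exceeds `ov_max` are removed.
#'
#' @param ppi PPI network: an igraph, a two-column edge data frame/matrix,
#'   or a path to an edge-list TSV.
#' @param expr Expression data: numeric matrix with gene rownames (columns
#'   are conditions/time points) or a path to an expression TSV.
#' @param alpha Weight of the clustering-factor term in PTC, in \[0, 1\]
#'   (default 0.8).
#' @param lambda Expansion gate on edge weight, in (0, 1) (default 0.7).
#' @param ov_max Maximum tolerated inter-module Jaccard overlap, in
#'   (0, 1\] (default 0.8).
#' @param min_size Smallest module size kept (default 3).
#' @param cn_combine,missing_policy,clamp_gec,similarity Passed to
#'   [build_weighted_network()].
#' @param mode Seed-consumption semantics, see [detect_modules()].
#' @return Object of class `ectg` with components `modules`
#'   (`ectg_modules`), `network` (`weighted_ppi`), `params`, `report` and
#'   `call`. Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' sim <- planted_truth(n_modules = 2, size_range = c(5, 6),
#'                      n_background = 10, seed = 1)
#' fit <- ectg(generate_network(sim), generate_expression(sim),
#'             lambda = 0.4)
#' fit
#' as.data.frame(fit)
#' @export
ectg <- function(ppi, expr, alpha = 0.8, lambda = 0.7, ov_max = 0.8,
                 min_size = 3, cn_combine = c("mean", "min", "max"),
                 missing_policy = c("drop", "zero"), clamp_gec = TRUE,
                 similarity = c("jackknife", "pearson", "cosine"),
                 mode = c("overlap", "strict")) {
  cl <- match.call()
  w <- build_weighted_network(ppi, expr, alpha = alpha,
                              cn_combine = match.arg(cn_combine),
                              missing_policy = match.arg(missing_policy),
                              clamp_gec = clamp_gec,
                              similarity = match.arg(similarity))
  mods <- detect_modules(w, lambda = lambda, ov_max = ov_max,
                         min_size = min_size, mode = match.arg(mode))
  structure(list(modules = mods,
                 network = w,
                 params = c(w$params,
                            list(lambda = lambda, ov_max = ov_max,
                                 min_size = min_size,
                                 mode = match.arg(mode))),
                 report = w$report,
                 call = cl),
            class = "ectg")
}

#' @export
print.ectg <- function(x, ...) {
  cat("Protein functional module detection (topology x coexpression)\n")
  cat("Call: "); print(x$call)
  p <- x$params
  cat(sprintf("Parameters: alpha = %g, lambda = %g, ov_max = %g, min_size = %d\n",
              p$alpha, p$lambda, p$ov_max, p$min_size))
  cat(sprintf("Network: %d nodes, %d weighted edges\n",
              x$report$nodes_out, x$report$edges_out))
  sz <- vapply(module_members(x), length, integer(1))
  if (length(sz))
    cat(sprintf("Modules: %d (sizes %d-%d, median %g)\n",
                length(sz), min(sz), max(sz), stats::median(sz)))
  else cat("Modules: none retained\n")
  invisible(x)
}

#' @export
summary.ectg <- function(object, ...) {
  mem <- module_members(object)
  sz <- vapply(mem, length, integer(1))
  e <- object$network$edges
  out <- list(
    call = object$call,
    params = object$params,
    report = object$report,
    n_modules = length(mem),
    size_summary = if (length(sz)) summary(sz) else NULL,
    coverage_nodes = length(unique(unlist(mem))),
    omega_summary = summary(e$omega),
    gec_summary = summary(e$gec_raw),
    top_modules = utils::head(as.data.frame(object), 5))
  class(out) <- "summary.ectg"
  out
}

#' @export
print.summary.ectg <- function(x, ...) {
  cat("Protein functional module detection - summary\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Weighted network: %d nodes, %d edges (of %d/%d input)\n",
              x$report$nodes_out, x$report$edges_out,
              x$report$nodes_in, x$report$edges_in))
  cat("Edge weight omega:\n"); print(x$omega_summary)
  cat("Raw coexpression (GEC):\n"); print(x$gec_summary)
  cat(sprintf("Retained modules: %d, covering %d proteins\n",
              x$n_modules, x$coverage_nodes))
  if (!is.null(x$size_summary)) {
    cat("Module sizes:\n"); print(x$size_summary)
    cat("Largest-weight modules:\n"); print(x$top_modules)
  }
  invisible(x)
}

#' @export
as.data.frame.ectg <- function(x, ...) {
  as.data.frame(x$modules, ...)
}

#' @export
as.data.frame.ectg_modules <- function(x, ...) {
  xs <- unclass(x)
  if (length(xs) == 0)
    return(data.frame(module_id = character(), size = integer(),
                      internal_weight = numeric(), members = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    module_id = sprintf("M%03d", seq_along(xs)),
    size = vapply(xs, function(m) length(m$members), integer(1)),
    internal_weight = vapply(xs, `[[`, numeric(1), "internal_weight"),
    members = vapply(xs, function(m) paste(m$members, collapse = ", "),
                     character(1)),
    stringsAsFactors = FALSE)
}

#' Plot a fitted module detection
#'
#' Draws the weighted network with retained modules coloured; background
#' (unassigned) nodes are grey.
#'
#' @param x An `ectg` fit.
#' @param ... Passed on to [igraph::plot.igraph()].
#' @export
plot.ectg <- function(x, ...) {
  g <- x$network$graph
  mem <- module_members(x)
  col <- rep("grey80", igraph::vcount(g))
  if (length(mem)) {
    pal <- grDevices::hcl.colors(max(3, length(mem)), "Dark 3")
    for (i in seq_along(mem))
      col[igraph::V(g)$name %in% mem[[i]]] <- pal[i]
  }
  ew <- igraph::E(g)$omega
  igraph::plot.igraph(g, vertex.color = col, vertex.size = 6,
                      vertex.label = NA,
                      edge.width = 0.5 + 2.5 * ew / max(ew, 1e-9), ...)
  invisible(x)
}
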