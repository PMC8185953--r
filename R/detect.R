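## The clustering engine: greedy maximum-weight seed-edge selection,
## threshold-gated breadth-first expansion, minimum-size filter and
## maximum-overlap (Jaccard) redundancy filter.
##
## Semantics that matter for reproducibility:
##   * a seed edge is eligible only while neither endpoint has belonged to
##     any previously grown module; expansion, however, may absorb nodes
##     already used elsewhere, which is where module overlap arises and why
##     the OvMax filter exists (a strict-disjoint mode disables this);
##   * the expansion gate is inclusive (weight >= lambda); the overlap
##     filter is strict (drop when score > ov_max);
##   * every tie is broken lexicographically on identifiers, so identical
##     inputs always give identical output.

.detect_env <- function(w) {
  stopifnot(inherits(w, "weighted_ppi"))
  nm <- igraph::V(w$graph)$name
  idx <- setNames(seq_along(nm), nm)
  ne <- nrow(w$edges)
  adj <- vector("list", length(nm))
  wts <- vector("list", length(nm))
  ui <- idx[w$edges$u]; vi <- idx[w$edges$v]
  for (k in seq_len(ne)) {
    adj[[ui[k]]] <- c(adj[[ui[k]]], vi[k])
    adj[[vi[k]]] <- c(adj[[vi[k]]], ui[k])
    wts[[ui[k]]] <- c(wts[[ui[k]]], w$edges$omega[k])
    wts[[vi[k]]] <- c(wts[[vi[k]]], w$edges$omega[k])
  }
  list(names = nm, idx = idx, adj = adj, wts = wts,
       eu = ui, ev = vi, ew = w$edges$omega,
       elab_u = w$edges$u, elab_v = w$edges$v)
}

#' Select the next seed edge
#'
#' Returns the maximum-weight edge among those whose endpoints are both
#' outside `consumed`, breaking weight ties lexicographically on the sorted
#' endpoint pair; `NULL` when no eligible edge remains (the detector's
#' termination signal).
#'
#' @param w A `weighted_ppi` object.
#' @param consumed Character vector of node names already claimed by
#'   earlier modules.
#' @return List with `u`, `v`, `omega`, or `NULL`.
#' @export
select_seed_edge <- function(w, consumed = character()) {
  stopifnot(inherits(w, "weighted_ppi"))
  e <- w$edges
  free <- !(e$u %in% consumed) & !(e$v %in% consumed)
  if (!any(free)) return(NULL)
  cand <- which(free)
  cand <- cand[order(-e$omega[cand], e$u[cand], e$v[cand],
                     method = "radix")]
  k <- cand[1]
  list(u = e$u[k], v = e$v[k], omega = e$omega[k])
}

#' Expand a seed edge into a module by gated breadth-first search
#'
#' Starting from the seed endpoints, every node adjacent to a current
#' member joins the module if the connecting edge weighs at least `lambda`;
#' sweeps repeat until a full pass adds nothing. The absorption rule is
#' monotone in the member set, so the result does not depend on
#' within-sweep scan order.
#'
#' @param w A `weighted_ppi` object.
#' @param seed_edge A list/vector with the two endpoint names (as returned
#'   by [select_seed_edge()]).
#' @param lambda Expansion gate in (0, 1); an edge joins a neighbour only
#'   if its weight is `>= lambda`.
#' @param restrict Optional character vector: only these nodes may be
#'   absorbed (used by the strict-disjoint mode).
#' @return Character vector of member names, sorted.
#' @export
expand_seed <- function(w, seed_edge, lambda, restrict = NULL) {
  stopifnot(inherits(w, "weighted_ppi"))
  .check_lambda(lambda)
  su <- as.character(seed_edge[["u"]] %||% seed_edge[[1]])
  sv <- as.character(seed_edge[["v"]] %||% seed_edge[[2]])
  env <- .detect_env(w)
  .expand_idx(env, env$idx[[su]], env$idx[[sv]], lambda,
              restrict = if (is.null(restrict)) NULL else
                unname(env$idx[intersect(restrict, names(env$idx))]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda <= 0 || lambda >= 1)
    stop("lambda must lie strictly between 0 and 1", call. = FALSE)
  invisible(TRUE)
}

# core expansion on integer indices; returns sorted member names
.expand_idx <- function(env, i, j, lambda, restrict = NULL) {
  if (is.na(i) || is.na(j))
    stop("seed endpoints not found in the weighted network", call. = FALSE)
  n <- length(env$names)
  member <- logical(n)
  member[c(i, j)] <- TRUE
  allowed <- if (is.null(restrict)) rep(TRUE, n) else {
    a <- logical(n); a[restrict] <- TRUE; a[c(i, j)] <- TRUE; a
  }
  frontier <- c(i, j)
  while (length(frontier)) {
    nxt <- integer(0)
    for (k in frontier) {
      nb <- env$adj[[k]]
      ok <- nb[!member[nb] & allowed[nb] & env$wts[[k]] >= lambda]
      if (length(ok)) {
        member[ok] <- TRUE
        nxt <- c(nxt, ok)
      }
    }
    frontier <- unique(nxt)
  }
  sort(env$names[member])
}

#' Overlap score of a module against a collection
#'
#' Maximum Jaccard index `|e n PC| / |e u PC|` of the member set against
#' every other module; 0 for an empty collection.
#'
#' @param e Character vector of member names.
#' @param others List of character vectors.
#' @return Scalar in \[0, 1\].
#' @export
overlap_score <- function(e, others) {
  if (length(others) == 0) return(0)
  e <- unique(e)
  max(vapply(others, function(o) {
    o <- unique(o)
    length(intersect(e, o)) / length(union(e, o))
  }, numeric(1)))
}

#' Detect protein complexes on a weighted PPI network
#'
#' Repeats seed selection ([select_seed_edge()]) and gated expansion
#' ([expand_seed()]), marking every grown member as consumed, until no
#' eligible seed edge remains; then removes modules smaller than
#' `min_size`, and finally — in creation order — removes any module whose
#' overlap score against the already-retained set exceeds `ov_max`.
#'
#' @param w A `weighted_ppi` object.
#' @param lambda Expansion gate in (0, 1) (default 0.7).
#' @param ov_max Maximum tolerated overlap score in (0, 1\] (default 0.8);
#'   a module is dropped when its score is strictly greater.
#' @param min_size Minimum module size kept (default 3).
#' @param mode `"overlap"` (default: expansion may absorb consumed nodes)
#'   or `"strict"` (modules are forced pairwise disjoint).
#' @return Object of class `ectg_modules`: a list of modules, each a list
#'   with `members` (sorted character vector), `seed` (u, v, omega),
#'   `internal_weight` (sum of within-module edge weights) and
#'   `order_index` (creation rank, 1-based, before filtering).
#' @export
detect_modules <- function(w, lambda = 0.7, ov_max = 0.8, min_size = 3,
                           mode = c("overlap", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(w, "weighted_ppi"))
  .check_lambda(lambda)
  if (!is.numeric(ov_max) || length(ov_max) != 1 || is.na(ov_max) ||
      ov_max <= 0 || ov_max > 1)
    stop("ov_max must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(min_size) || min_size < 1)
    stop("min_size must be a positive integer", call. = FALSE)

  env <- .detect_env(w)
  n <- length(env$names)
  consumed <- logical(n)
  mods <- list()
  ord <- order(-env$ew, env$elab_u, env$elab_v, method = "radix")
  repeat {
    k <- NA_integer_
    for (kk in ord) {
      if (!consumed[env$eu[kk]] && !consumed[env$ev[kk]]) { k <- kk; break }
    }
    if (is.na(k)) break
    members <- .expand_idx(env, env$eu[k], env$ev[k], lambda,
                           restrict = if (mode == "strict")
                             which(!consumed) else NULL)
    mi <- unname(env$idx[members])
    consumed[mi] <- TRUE
    mods[[length(mods) + 1L]] <- list(
      members = members,
      seed = list(u = env$elab_u[k], v = env$elab_v[k], omega = env$ew[k]),
      internal_weight = .internal_weight(env, mi),
      order_index = length(mods) + 1L)
  }

  mods <- Filter(function(m) length(m$members) >= min_size, mods)
  kept <- filter_modules_by_overlap(mods, ov_max)
  structure(kept,
            class = "ectg_modules",
            params = list(lambda = lambda, ov_max = ov_max,
                          min_size = min_size, mode = mode))
}

#' Remove redundant modules by maximum-overlap filtering
#'
#' Walks the modules in creation order and drops any whose overlap score
#' ([overlap_score()]) against the already-retained set is strictly greater
#' than `ov_max`; earlier-created modules always win.
#'
#' With the default expansion-to-closure semantics every detected module is
#' a connected component of the lambda-thresholded subgraph, so detected
#' modules are already pairwise disjoint and this filter passes them
#' through; it bites when modules come from other sources (partial
#' expansions, merged runs, external predictions).
#'
#' @param modules List of modules: either detector records (with a
#'   `members` field) or plain character vectors.
#' @param ov_max Maximum tolerated overlap score, in (0, 1\].
#' @return The retained sublist, in the original order.
#' @export
filter_modules_by_overlap <- function(modules, ov_max) {
  if (!is.numeric(ov_max) || length(ov_max) != 1 || is.na(ov_max) ||
      ov_max <= 0 || ov_max > 1)
    stop("ov_max must lie in (0, 1]", call. = FALSE)
  members_of <- function(m) if (is.list(m)) m$members else m
  kept <- list()
  for (m in modules) {
    ov <- overlap_score(members_of(m), lapply(kept, members_of))
    if (ov <= ov_max) kept[[length(kept) + 1L]] <- m
  }
  kept
}

.internal_weight <- function(env, mi) {
  inside <- logical(length(env$names))
  inside[mi] <- TRUE
  sum(env$ew[inside[env$eu] & inside[env$ev]])
}

#' @export
print.ectg_modules <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("%d detected module(s) (lambda = %g, ov_max = %g, min_size = %d)\n",
              length(x), p$lambda, p$ov_max, p$min_size))
  if (length(x)) {
    sz <- vapply(x, function(m) length(m$members), integer(1))
    cat(sprintf("  sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
  }
  invisible(x)
}

#' Member sets of detected modules
#'
#' @param x An `ectg_modules` object or an `ectg` fit.
#' @return List of character vectors.
#' @export
module_members <- function(x) {
  if (inherits(x, "ectg")) x <- x$modules
  if (is.list(x)) {
    xs <- unclass(x)
    if (length(xs) == 0) return(list())
    if (all(vapply(xs, function(m) is.list(m) && !is.null(m$members),
                   logical(1))))
      return(lapply(xs, `[[`, "members"))
    if (all(vapply(xs, is.character, logical(1))))
      return(xs)
  }
  stop("cannot extract module members", call. = FALSE)
}
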