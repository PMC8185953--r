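## Synthetic benchmark generator: a planted-partition PPI network plus an
## expression matrix in which members of a planted module share a smooth
## latent time-course profile. Stands in for curated interaction networks,
## time-series expression and a reference complex catalog, so the whole
## pipeline can be exercised end to end without external downloads.

#' Define a planted-module ground truth
#'
#' Module sizes are drawn uniformly from `size_range`; members and
#' background proteins get sequential identifiers. Modules are pairwise
#' disjoint unless `overlap > 0`, in which case each module after the first
#' re-uses that many members of the previous one (for exercising the
#' overlap filter).
#'
#' @param n_modules Number of planted modules (default 5).
#' @param size_range Length-2 integer range of module sizes (default
#'   `c(6, 10)`).
#' @param n_background Number of background proteins outside any module
#'   (default 100).
#' @param p_in Intra-module edge probability (default 0.9).
#' @param p_out Background edge probability for every other pair (default
#'   0.02); must be < `p_in`.
#' @param overlap Members shared between consecutive modules (default 0).
#' @param seed Integer RNG seed; all downstream generation derives from it.
#' @return Object of class `planted_truth`: list with `modules` (named list
#'   of member-id vectors), `proteins`, `p_in`, `p_out`, `seed`.
#' @export
planted_truth <- function(n_modules = 5, size_range = c(6, 10),
                          n_background = 100, p_in = 0.9, p_out = 0.02,
                          overlap = 0, seed = 1) {
  stopifnot(n_modules >= 1, length(size_range) == 2,
            size_range[1] >= 2, size_range[2] >= size_range[1],
            n_background >= 0, overlap >= 0,
            overlap < size_range[1])
  if (!(p_out < p_in && p_in <= 1 && p_out >= 0))
    stop("need 0 <= p_out < p_in <= 1", call. = FALSE)
  seed <- as.integer(seed)
  set.seed(seed)
  size_choices <- seq(size_range[1], size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), n_modules,
                                   replace = TRUE)]
  n_mod_prot <- sum(sizes) - overlap * (n_modules - 1)
  ids <- sprintf("P%04d", seq_len(n_mod_prot + n_background))
  modules <- vector("list", n_modules)
  pos <- 0
  for (i in seq_len(n_modules)) {
    if (i == 1 || overlap == 0) {
      modules[[i]] <- ids[pos + seq_len(sizes[i])]
      pos <- pos + sizes[i]
    } else {
      shared <- utils::tail(modules[[i - 1]], overlap)
      fresh <- ids[pos + seq_len(sizes[i] - overlap)]
      modules[[i]] <- c(shared, fresh)
      pos <- pos + sizes[i] - overlap
    }
  }
  names(modules) <- sprintf("PM%02d", seq_len(n_modules))
  structure(list(modules = modules, proteins = ids,
                 n_background = n_background,
                 p_in = p_in, p_out = p_out, overlap = overlap,
                 seed = seed),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf(
    "Planted truth: %d modules (sizes %s), %d background proteins, p_in = %g, p_out = %g, seed = %d\n",
    length(x$modules),
    paste(range(lengths(x$modules)), collapse = "-"),
    x$n_background, x$p_in, x$p_out, x$seed))
  invisible(x)
}

# deterministic sub-seed: keep within 32-bit signed range
.sub_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7 + stream * 104729) %% 2147483647)
}

#' Generate the planted-module PPI network
#'
#' Each intra-module protein pair is connected with probability `p_in`,
#' every other pair with `p_out`. Reproducible: the edge set is a pure
#' function of the truth's seed.
#'
#' @param truth A `planted_truth` object.
#' @return An undirected simple `igraph` over `truth$proteins`.
#' @export
generate_network <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  set.seed(.sub_seed(truth$seed, 1L))
  ids <- truth$proteins
  n <- length(ids)
  memb <- lapply(truth$modules, function(m) match(m, ids))
  intra <- matrix(FALSE, n, n)
  for (m in memb)
    intra[m, m] <- TRUE
  pr <- ifelse(intra, truth$p_in, truth$p_out)
  ut <- upper.tri(pr)
  edge <- ut & matrix(runif(n * n), n, n) < pr
  idx <- which(edge, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  igraph::simplify(g)
}

#' Generate module-correlated expression profiles
#'
#' Every planted module draws one latent smooth profile — a cumulative sum
#' of Gaussian steps, mimicking a time-course trajectory — and each member
#' observes it plus independent Gaussian noise. Background proteins get
#' independent latent profiles of their own. With `overlap > 0`, a protein
#' in several modules follows the latent profile of its first module.
#'
#' @param truth A `planted_truth` object.
#' @param n_conditions Number of conditions/time points (default 28).
#' @param noise_sd Standard deviation of the member-level observation noise
#'   (default 0.2, in the same units as the latent profile).
#' @param step_sd Standard deviation of the latent random-walk steps
#'   (default 0.3; sets the signal scale against which `noise_sd` acts).
#' @return Numeric matrix, rows = proteins, columns = conditions.
#' @export
generate_expression <- function(truth, n_conditions = 28, noise_sd = 0.2,
                                step_sd = 0.3) {
  stopifnot(inherits(truth, "planted_truth"))
  if (n_conditions < 4)
    stop("need at least 4 conditions for the Jackknife sweep", call. = FALSE)
  if (noise_sd < 0 || step_sd <= 0)
    stop("noise_sd must be >= 0 and step_sd > 0", call. = FALSE)
  set.seed(.sub_seed(truth$seed, 2L))
  ids <- truth$proteins
  latent <- vapply(seq_along(truth$modules),
                   function(i) cumsum(rnorm(n_conditions, 0, step_sd)),
                   numeric(n_conditions))
  assign_mod <- rep(NA_integer_, length(ids))
  for (i in rev(seq_along(truth$modules)))
    assign_mod[match(truth$modules[[i]], ids)] <- i
  expr <- matrix(NA_real_, length(ids), n_conditions,
                 dimnames = list(ids, sprintf("T%02d",
                                              seq_len(n_conditions))))
  for (k in seq_along(ids)) {
    expr[k, ] <- if (is.na(assign_mod[k]))
      cumsum(rnorm(n_conditions, 0, step_sd))
    else
      latent[, assign_mod[k]] + rnorm(n_conditions, 0, noise_sd)
  }
  expr
}

#' Planted modules as a reference catalog
#'
#' @param truth A `planted_truth` object.
#' @return List of character vectors usable as the `ref` argument of
#'   [evaluate_modules()].
#' @export
truth_as_catalog <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  lapply(truth$modules, function(m) sort(unique(m)))
}

#' Planted modules as an annotation map
#'
#' Each planted module becomes one annotation term covering its members;
#' background proteins are annotated with a shared background term so the
#' annotation universe spans all proteins.
#'
#' @param truth A `planted_truth` object.
#' @return Named list term -> protein vector, for [enrichment_summary()].
#' @export
truth_as_annotations <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  ann <- truth$modules
  names(ann) <- sprintf("TERM_%s", names(truth$modules))
  bg <- setdiff(truth$proteins, unlist(truth$modules))
  if (length(bg)) ann$TERM_BACKGROUND <- bg
  lapply(ann, sort)
}

#' Write a synthetic benchmark to disk
#'
#' Writes `<prefix>_ppi.tsv`, `<prefix>_expr.tsv` and `<prefix>_truth.tsv`
#' (the planted catalog), ready for [run_pipeline()].
#'
#' @param truth A `planted_truth` object.
#' @param prefix Output path prefix.
#' @param n_conditions,noise_sd,step_sd Passed to [generate_expression()].
#' @return Named character vector of the three written paths, invisibly.
#' @export
write_synthetic_benchmark <- function(truth, prefix, n_conditions = 28,
                                      noise_sd = 0.2, step_sd = 0.3) {
  paths <- c(ppi = paste0(prefix, "_ppi.tsv"),
             expr = paste0(prefix, "_expr.tsv"),
             truth = paste0(prefix, "_truth.tsv"))
  write_ppi_edges(generate_network(truth), paths[["ppi"]])
  write_expression_matrix(
    generate_expression(truth, n_conditions, noise_sd, step_sd),
    paths[["expr"]])
  write_complex_catalog(truth_as_catalog(truth), paths[["truth"]])
  invisible(paths)
}
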