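## Benchmark evaluation against a reference complex catalog and
## hypergeometric functional-enrichment scoring.
##
## A predicted module "hits" a known complex when the neighbourhood
## affinity |A n B|^2 / (|A| * |B|) reaches the matching threshold
## (0.2 by default, the de-facto convention in the complex-detection
## benchmarking literature; Jaccard is available as an alternative).
## Precision is the fraction of predictions hitting some known complex,
## recall the fraction of known complexes hit by some prediction, and the
## F-measure their harmonic mean. The coverage rate CR is defined here as
## the fraction of distinct benchmark proteins that appear in at least one
## predicted module — a reconstruction, since the benchmark literature's
## tables report CR without defining it.

.as_member_sets <- function(x, what = "modules") {
  sets <- tryCatch(module_members(x), error = function(e) NULL)
  if (is.null(sets))
    stop(sprintf("cannot interpret %s as a collection of protein sets", what),
         call. = FALSE)
  lapply(sets, function(s) unique(as.character(s)))
}

#' Matching score between a predicted and a known protein set
#'
#' @param a,b Nonempty character vectors of protein identifiers.
#' @param method `"affinity"` (default): neighbourhood affinity
#'   `|a n b|^2 / (|a| |b|)`; `"jaccard"`: `|a n b| / |a u b|`.
#' @return Scalar in \[0, 1\]; symmetric in its arguments.
#' @examples
#' matching_score(c("a", "b", "c", "d"), c("c", "d", "e")) # 4/12
#' @export
matching_score <- function(a, b, method = c("affinity", "jaccard")) {
  method <- match.arg(method)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0 || length(b) == 0)
    stop("matching score needs two nonempty protein sets", call. = FALSE)
  i <- length(intersect(a, b))
  switch(method,
         affinity = i^2 / (length(a) * length(b)),
         jaccard = i / length(union(a, b)))
}

#' F-measure from precision and recall
#'
#' `F = 2PR / (P + R)`, defined as 0 when both are 0.
#'
#' @param precision,recall Values in \[0, 1\] (vectorized).
#' @return Harmonic mean, in \[min(P, R), max(P, R)\].
#' @export
f_measure <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

#' Coverage rate of a benchmark by predicted modules
#'
#' Fraction of distinct proteins occurring in the reference complexes that
#' are members of at least one predicted module.
#'
#' @param pred Predicted modules (an `ectg` fit, `ectg_modules`, or list of
#'   character vectors).
#' @param ref Reference catalog (list of character vectors, e.g. from
#'   [read_complex_catalog()] or [truth_as_catalog()]).
#' @return Scalar in \[0, 1\].
#' @export
coverage_rate <- function(pred, ref) {
  refs <- .as_member_sets(ref, "the reference catalog")
  if (length(refs) == 0)
    stop("reference catalog is empty", call. = FALSE)
  preds <- tryCatch(.as_member_sets(pred), error = function(e) list())
  bench <- unique(unlist(refs))
  covered <- unique(unlist(preds))
  length(intersect(bench, covered)) / length(bench)
}

#' Evaluate predicted modules against a reference catalog
#'
#' @inheritParams coverage_rate
#' @param match_threshold Minimum matching score counting as a hit, in
#'   (0, 1\] (default 0.2).
#' @param method Matching score variant, see [matching_score()].
#' @return Object of class `ectg_eval`: list with `precision`, `recall`,
#'   `fmeasure`, `coverage`, `n_pred`, `n_ref`, `pred_matched` and
#'   `ref_matched` logical vectors, and the matching settings.
#' @export
evaluate_modules <- function(pred, ref, match_threshold = 0.2,
                             method = c("affinity", "jaccard")) {
  method <- match.arg(method)
  if (!is.numeric(match_threshold) || match_threshold <= 0 ||
      match_threshold > 1)
    stop("match_threshold must lie in (0, 1]", call. = FALSE)
  preds <- .as_member_sets(pred)
  refs <- .as_member_sets(ref, "the reference catalog")
  if (length(refs) == 0)
    stop("reference catalog is empty", call. = FALSE)
  if (length(preds) == 0) {
    pred_matched <- logical(0)
    ref_matched <- rep(FALSE, length(refs))
  } else {
    score <- vapply(refs, function(r)
      vapply(preds, matching_score, numeric(1), b = r, method = method),
      numeric(length(preds)))
    score <- matrix(score, nrow = length(preds))
    hit <- score >= match_threshold
    pred_matched <- apply(hit, 1, any)
    ref_matched <- apply(hit, 2, any)
  }
  precision <- if (length(preds)) mean(pred_matched) else 0
  recall <- mean(ref_matched)
  structure(list(precision = precision,
                 recall = recall,
                 fmeasure = f_measure(precision, recall),
                 coverage = coverage_rate(preds, refs),
                 n_pred = length(preds),
                 n_ref = length(refs),
                 pred_matched = pred_matched,
                 ref_matched = ref_matched,
                 match_threshold = match_threshold,
                 method = method),
            class = "ectg_eval")
}

#' @export
print.ectg_eval <- function(x, ...) {
  cat(sprintf(
    "Benchmark evaluation (%s matching, threshold %g)\n",
    x$method, x$match_threshold))
  cat(sprintf("  predictions: %d, reference complexes: %d\n",
              x$n_pred, x$n_ref))
  cat(sprintf("  CR = %.3f  precision = %.3f  recall = %.3f  F = %.3f\n",
              x$coverage, x$precision, x$recall, x$fmeasure))
  invisible(x)
}

#' Hypergeometric enrichment tail probability
#'
#' Probability of observing at least `x` annotated proteins in a module of
#' size `n` drawn without replacement from a background of `N` proteins of
#' which `M` carry the annotation:
#' `P = sum_{i=x}^{n} C(M, i) C(N - M, n - i) / C(N, n)`.
#' Evaluated in log space (log-gamma binomials combined by log-sum-exp) so
#' tails at the 1e-35 scale are returned without underflow; `x = 0` gives
#' exactly 1.
#'
#' @param N Background size (annotated universe).
#' @param M Proteins carrying the term, `M <= N`.
#' @param n Module size, `n <= N`.
#' @param x Module members carrying the term, `0 <= x <= min(M, n)`.
#' @return P-value in (0, 1\].
#' @examples
#' hypergeom_pvalue(10, 5, 5, 5) # 1/252
#' @export
hypergeom_pvalue <- function(N, M, n, x) {
  for (a in list(N, M, n, x))
    if (!is.numeric(a) || length(a) != 1 || is.na(a) || a < 0 ||
        a != round(a))
      stop("N, M, n, x must be single non-negative integers", call. = FALSE)
  if (M > N || n > N)
    stop("need M <= N and n <= N", call. = FALSE)
  if (x > min(M, n))
    stop("x cannot exceed min(M, n)", call. = FALSE)
  if (x == 0) return(1)
  i <- seq.int(x, min(n, M))
  if (length(i) == 0) return(0)
  # terms with n - i > N - M have zero probability (impossible draws)
  i <- i[(n - i) <= (N - M)]
  if (length(i) == 0) return(0)
  lt <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  mx <- max(lt)
  min(1, exp(mx) * sum(exp(lt - mx)))
}

#' Functional-enrichment summary of detected modules
#'
#' For every module the best (smallest) hypergeometric P-value over all
#' annotation terms is recorded; the summary reports, per threshold, the
#' percentage of modules whose best P-value is strictly below it, plus the
#' mean of `-log10(best P)` across modules.
#'
#' The background `N` is the union of all annotated proteins, and a
#' module's draw size is its count of annotated members; modules with no
#' annotated member score best P = 1 and are counted (and reported) as
#' unannotatable.
#'
#' @param modules Modules (an `ectg` fit, `ectg_modules`, or list of
#'   character vectors).
#' @param annotations Named list term -> character vector of proteins
#'   (e.g. from [read_annotations()]).
#' @param thresholds Numeric vector of significance cutoffs (default
#'   `c(1e-15, 1e-10, 1e-5, 1e-2)`).
#' @return Object of class `ectg_enrichment`: list with `per_module` (data
#'   frame: module, size, n_annotated, best_term, best_p), `percent_below`
#'   (named vector of percentages per threshold), `avg_neglog10_p`, and
#'   `n_unannotated`.
#' @export
enrichment_summary <- function(modules, annotations,
                               thresholds = c(1e-15, 1e-10, 1e-5, 1e-2)) {
  mem <- .as_member_sets(modules)
  if (length(mem) == 0)
    stop("no modules to score", call. = FALSE)
  if (!is.list(annotations) || is.null(names(annotations)) ||
      length(annotations) == 0)
    stop("annotations must be a nonempty named list (term -> proteins)",
         call. = FALSE)
  if (!is.numeric(thresholds) || length(thresholds) == 0 ||
      any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  annotations <- lapply(annotations, function(p) unique(as.character(p)))
  background <- unique(unlist(annotations))
  N <- length(background)
  M <- vapply(annotations, length, integer(1))

  best_p <- numeric(length(mem))
  best_term <- character(length(mem))
  n_ann <- integer(length(mem))
  for (k in seq_along(mem)) {
    members <- intersect(mem[[k]], background)
    n <- length(members)
    n_ann[k] <- n
    if (n == 0) { best_p[k] <- 1; best_term[k] <- NA_character_; next }
    p <- vapply(seq_along(annotations), function(t) {
      x <- length(intersect(members, annotations[[t]]))
      hypergeom_pvalue(N, M[[t]], n, x)
    }, numeric(1))
    j <- which.min(p)
    best_p[k] <- p[j]
    best_term[k] <- names(annotations)[j]
  }
  if (any(n_ann == 0))
    message(sprintf("%d module(s) have no annotated members; best P set to 1",
                    sum(n_ann == 0)))
  pct <- vapply(thresholds, function(t) 100 * mean(best_p < t), numeric(1))
  names(pct) <- format(thresholds, scientific = TRUE, digits = 3)
  structure(list(
    per_module = data.frame(
      module = sprintf("M%03d", seq_along(mem)),
      size = vapply(mem, length, integer(1)),
      n_annotated = n_ann, best_term = best_term, best_p = best_p,
      stringsAsFactors = FALSE),
    percent_below = pct,
    thresholds = thresholds,
    avg_neglog10_p = mean(-log10(pmax(best_p, .Machine$double.xmin))),
    n_unannotated = sum(n_ann == 0),
    background_size = N),
    class = "ectg_enrichment")
}

#' @export
print.ectg_enrichment <- function(x, ...) {
  cat(sprintf("Functional enrichment over %d module(s), background %d proteins\n",
              nrow(x$per_module), x$background_size))
  cat(sprintf("  mean -log10(best P) = %.2f", x$avg_neglog10_p))
  if (x$n_unannotated > 0)
    cat(sprintf("  (%d unannotated module(s))", x$n_unannotated))
  cat("\n  % of modules with best P below threshold:\n")
  for (i in seq_along(x$percent_below))
    cat(sprintf("    < %s : %.2f%%\n", names(x$percent_below)[i],
                x$percent_below[i]))
  invisible(x)
}
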