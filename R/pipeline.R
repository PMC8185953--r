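## Pipeline driver: validated run configuration, the end-to-end run
## (weight -> detect -> evaluate -> enrich) with a machine-readable
## manifest, and the parameter sweep used to map the alpha/lambda/ov_max
## response surface.

#' Build a validated run configuration
#'
#' @param ppi,expr Required input paths (edge-list TSV, expression TSV).
#' @param ref Optional reference catalog path (enables evaluation).
#' @param annotations Optional annotation TSV path (enables enrichment).
#' @param out_dir Output directory (default `"ectg_out"`).
#' @param alpha,lambda,ov_max,min_size Detection parameters (defaults 0.8,
#'   0.7, 0.8, 3).
#' @param match_threshold Matching threshold for evaluation (default 0.2).
#' @param missing_policy,clamp_gec,cn_combine,similarity,mode Passed to
#'   [ectg()].
#' @param enrich_thresholds Enrichment significance cutoffs.
#' @return Object of class `ectg_config`.
#' @export
ectg_config <- function(ppi, expr, ref = NULL, annotations = NULL,
                        out_dir = "ectg_out",
                        alpha = 0.8, lambda = 0.7, ov_max = 0.8,
                        min_size = 3, match_threshold = 0.2,
                        missing_policy = "drop", clamp_gec = TRUE,
                        cn_combine = "mean", similarity = "jackknife",
                        mode = "overlap",
                        enrich_thresholds = c(1e-15, 1e-10, 1e-5, 1e-2)) {
  .check_alpha(alpha)
  .check_lambda(lambda)
  if (ov_max <= 0 || ov_max > 1) stop("ov_max must lie in (0, 1]",
                                      call. = FALSE)
  if (min_size < 1) stop("min_size must be >= 1", call. = FALSE)
  if (match_threshold <= 0 || match_threshold > 1)
    stop("match_threshold must lie in (0, 1]", call. = FALSE)
  for (p in c(ppi, expr, ref, annotations))
    if (!file.exists(p)) stop(sprintf("input not found: %s", p),
                              call. = FALSE)
  structure(list(ppi = ppi, expr = expr, ref = ref,
                 annotations = annotations, out_dir = out_dir,
                 alpha = alpha, lambda = lambda, ov_max = ov_max,
                 min_size = min_size, match_threshold = match_threshold,
                 missing_policy = missing_policy, clamp_gec = clamp_gec,
                 cn_combine = cn_combine, similarity = similarity,
                 mode = mode, enrich_thresholds = enrich_thresholds),
            class = "ectg_config")
}

#' Run the full detection pipeline from files
#'
#' Reads the configured inputs, builds the weighted network, detects
#' modules, then — when a reference catalog and/or annotation map is
#' configured — evaluates and scores enrichment. Writes `modules.tsv`,
#' `weighted_network.tsv`, optional `evaluation.json` /
#' `enrichment.tsv`, and `manifest.json` (parameters, package version,
#' input MD5 checksums, output counts) under `out_dir`.
#'
#' @param cfg An `ectg_config` object.
#' @param quiet Suppress progress messages (default FALSE).
#' @return List with `fit` (the `ectg` object), `evaluation`
#'   (`ectg_eval` or NULL), `enrichment` (`ectg_enrichment` or NULL) and
#'   `manifest`, invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "ectg_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("[1/4] reading PPI network and expression data")
  g <- read_ppi_edges(cfg$ppi)
  expr <- read_expression_matrix(cfg$expr)
  say("      %d nodes, %d edges; %d expression profiles",
      igraph::vcount(g), igraph::ecount(g), nrow(expr))

  say("[2/4] reconstructing edge weights (alpha = %g)", cfg$alpha)
  fit <- ectg(g, expr, alpha = cfg$alpha, lambda = cfg$lambda,
              ov_max = cfg$ov_max, min_size = cfg$min_size,
              cn_combine = cfg$cn_combine,
              missing_policy = cfg$missing_policy,
              clamp_gec = cfg$clamp_gec, similarity = cfg$similarity,
              mode = cfg$mode)
  say("[3/4] detected %d module(s) (lambda = %g, ov_max = %g)",
      length(fit$modules), cfg$lambda, cfg$ov_max)
  write_modules(fit, file.path(cfg$out_dir, "modules.tsv"))
  write_weighted_network(fit$network,
                         file.path(cfg$out_dir, "weighted_network.tsv"))

  evaluation <- NULL
  if (!is.null(cfg$ref)) {
    evaluation <- evaluate_modules(fit, read_complex_catalog(cfg$ref),
                                   match_threshold = cfg$match_threshold)
    say("[4/4] evaluation: CR = %.3f, P = %.3f, R = %.3f, F = %.3f",
        evaluation$coverage, evaluation$precision, evaluation$recall,
        evaluation$fmeasure)
    jsonlite::write_json(
      evaluation[c("coverage", "precision", "recall", "fmeasure",
                   "n_pred", "n_ref", "match_threshold", "method")],
      file.path(cfg$out_dir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA)
  }
  enrichment <- NULL
  if (!is.null(cfg$annotations) && length(fit$modules) > 0) {
    enrichment <- enrichment_summary(fit, read_annotations(cfg$annotations),
                                     thresholds = cfg$enrich_thresholds)
    utils::write.table(enrichment$per_module,
                       file.path(cfg$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "ectg",
    version = as.character(utils::packageVersion("ectg")),
    parameters = cfg[c("alpha", "lambda", "ov_max", "min_size",
                       "match_threshold", "missing_policy", "clamp_gec",
                       "cn_combine", "similarity", "mode")],
    inputs = lapply(
      Filter(Negate(is.null),
             list(ppi = cfg$ppi, expr = cfg$expr, ref = cfg$ref,
                  annotations = cfg$annotations)),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    results = list(
      nodes = fit$report$nodes_out, edges = fit$report$edges_out,
      modules = length(fit$modules),
      fmeasure = if (is.null(evaluation)) NULL else evaluation$fmeasure))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(fit = fit, evaluation = evaluation,
                 enrichment = enrichment, manifest = manifest))
}

#' Sweep detection parameters against a reference
#'
#' Re-runs detection for every combination of the supplied `alpha`,
#' `lambda` and `ov_max` values (the weighted network is rebuilt once per
#' distinct `alpha` and reused across the gate/overlap grid) and evaluates
#' each against the reference catalog.
#'
#' @param ppi,expr Network and expression inputs (objects or paths).
#' @param ref Reference catalog (list of sets or path).
#' @param alpha,lambda,ov_max Numeric vectors of parameter values.
#' @param min_size,match_threshold,... Fixed settings passed through.
#' @return Data frame with one row per combination: `alpha`, `lambda`,
#'   `ov_max`, `n_modules`, `coverage`, `precision`, `recall`, `fmeasure`
#'   (NA where a run failed, with a warning).
#' @export
parameter_sweep <- function(ppi, expr, ref, alpha = 0.8,
                            lambda = seq(0.1, 0.9, by = 0.1),
                            ov_max = 0.8, min_size = 3,
                            match_threshold = 0.2, ...) {
  if (is.character(ref) && length(ref) == 1)
    ref <- read_complex_catalog(ref)
  grid <- expand.grid(alpha = alpha, lambda = lambda, ov_max = ov_max,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$alpha, grid$lambda, grid$ov_max), , drop = FALSE]
  out <- grid
  out$n_modules <- NA_integer_
  out$coverage <- out$precision <- out$recall <- out$fmeasure <- NA_real_
  g <- as_ppi_graph(ppi)
  if (is.character(expr) && length(expr) == 1)
    expr <- read_expression_matrix(expr)
  w <- NULL
  w_alpha <- NA_real_
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      if (is.null(w) || grid$alpha[i] != w_alpha) {
        w <- build_weighted_network(g, expr, alpha = grid$alpha[i], ...)
        w_alpha <- grid$alpha[i]
      }
      mods <- detect_modules(w, lambda = grid$lambda[i],
                             ov_max = grid$ov_max[i], min_size = min_size)
      ev <- evaluate_modules(mods, ref, match_threshold = match_threshold)
      list(n = length(mods), ev = ev)
    }, error = function(e) {
      warning(sprintf("sweep cell alpha=%g lambda=%g ov_max=%g failed: %s",
                      grid$alpha[i], grid$lambda[i], grid$ov_max[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      out$n_modules[i] <- res$n
      out$coverage[i] <- res$ev$coverage
      out$precision[i] <- res$ev$precision
      out$recall[i] <- res$ev$recall
      out$fmeasure[i] <- res$ev$fmeasure
    }
  }
  rownames(out) <- NULL
  out
}
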