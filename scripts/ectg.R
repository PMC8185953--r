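#!/usr/bin/env Rscript
# Command-line front end to the ectg package.
#
#   Rscript scripts/ectg.R <command> [options]
#
# Commands:
#   simulate  write a synthetic planted-module benchmark (ppi/expr/truth TSVs)
#   weight    build and export the weighted network
#   detect    run module detection, write modules.tsv
#   evaluate  score a module file against a reference catalog
#   enrich    hypergeometric enrichment of a module file
#   sweep     grid-sweep alpha/lambda/ov_max against a reference
#   run       full pipeline (weight + detect [+ evaluate] [+ enrich])
#
# Exit codes: 0 ok, 2 usage error, 3 data/run error.

suppressPackageStartupMessages({
  library(ectg)
  library(optparse)
})

usage_quit <- function(msg) { message(msg); quit(status = 2) }
`%||%` <- function(a, b) if (is.null(a)) b else a

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1)
  usage_quit("usage: ectg.R <simulate|weight|detect|evaluate|enrich|sweep|run> [options]")
cmd <- argv[1]
rest <- argv[-1]

opts_common <- list(
  make_option("--ppi", type = "character", help = "PPI edge-list TSV"),
  make_option("--expr", type = "character", help = "expression matrix TSV"),
  make_option("--alpha", type = "double", default = 0.8),
  make_option("--lam", type = "double", default = 0.7,
              help = "expansion gate lambda [default %default]"),
  make_option("--ovmax", type = "double", default = 0.8),
  make_option("--min-size", type = "integer", default = 3, dest = "min_size"),
  make_option("--missing-policy", type = "character", default = "drop",
              dest = "missing_policy"),
  make_option("--no-clamp-gec", action = "store_true", default = FALSE,
              dest = "no_clamp"),
  make_option("--out", type = "character", default = NULL))

need <- function(o, f) if (is.null(o[[f]]))
  usage_quit(sprintf("missing required option --%s", gsub("_", "-", f)))

run <- function(expr) tryCatch(expr, error = function(e) {
  message("error: ", conditionMessage(e)); quit(status = 3)
})

if (cmd == "simulate") {
  op <- parse_args(OptionParser(option_list = list(
    make_option("--modules", type = "integer", default = 5),
    make_option("--sizes", type = "character", default = "6-10"),
    make_option("--background", type = "integer", default = 100),
    make_option("--p-in", type = "double", default = 0.9, dest = "p_in"),
    make_option("--p-out", type = "double", default = 0.02, dest = "p_out"),
    make_option("--conditions", type = "integer", default = 28),
    make_option("--noise", type = "double", default = 0.2),
    make_option("--seed", type = "integer", default = 1),
    make_option("--out-prefix", type = "character", dest = "out_prefix"))),
    args = rest)
  need(op, "out_prefix")
  rng <- as.integer(strsplit(op$sizes, "-", fixed = TRUE)[[1]])
  if (length(rng) == 1) rng <- c(rng, rng)
  run({
    tr <- planted_truth(n_modules = op$modules, size_range = rng,
                        n_background = op$background, p_in = op$p_in,
                        p_out = op$p_out, seed = op$seed)
    paths <- write_synthetic_benchmark(tr, op$out_prefix,
                                       n_conditions = op$conditions,
                                       noise_sd = op$noise)
    message("wrote ", paste(paths, collapse = ", "))
  })
} else if (cmd %in% c("weight", "detect", "run")) {
  extra <- list(
    make_option("--ref", type = "character", default = NULL),
    make_option("--annotations", type = "character", default = NULL),
    make_option("--match-threshold", type = "double", default = 0.2,
                dest = "match_threshold"))
  op <- parse_args(OptionParser(option_list = c(opts_common, extra)),
                   args = rest)
  need(op, "ppi"); need(op, "expr")
  run({
    if (cmd == "weight") {
      need(op, "out")
      w <- build_weighted_network(read_ppi_edges(op$ppi),
                                  read_expression_matrix(op$expr),
                                  alpha = op$alpha,
                                  missing_policy = op$missing_policy,
                                  clamp_gec = !op$no_clamp)
      print(w)
      write_weighted_network(w, op$out)
    } else if (cmd == "detect") {
      need(op, "out")
      fit <- ectg(op$ppi, op$expr, alpha = op$alpha, lambda = op$lam,
                  ov_max = op$ovmax, min_size = op$min_size,
                  missing_policy = op$missing_policy,
                  clamp_gec = !op$no_clamp)
      print(fit)
      write_modules(fit, op$out)
    } else {
      cfg <- ectg_config(ppi = op$ppi, expr = op$expr, ref = op$ref,
                         annotations = op$annotations,
                         out_dir = op$out %||% "ectg_out",
                         alpha = op$alpha, lambda = op$lam,
                         ov_max = op$ovmax, min_size = op$min_size,
                         match_threshold = op$match_threshold,
                         missing_policy = op$missing_policy,
                         clamp_gec = !op$no_clamp)
      run_pipeline(cfg)
    }
  })
} else if (cmd == "evaluate") {
  op <- parse_args(OptionParser(option_list = list(
    make_option("--pred", type = "character"),
    make_option("--ref", type = "character"),
    make_option("--match-threshold", type = "double", default = 0.2,
                dest = "match_threshold"))), args = rest)
  need(op, "pred"); need(op, "ref")
  run(print(evaluate_modules(read_complex_catalog(op$pred),
                             read_complex_catalog(op$ref),
                             match_threshold = op$match_threshold)))
} else if (cmd == "enrich") {
  op <- parse_args(OptionParser(option_list = list(
    make_option("--pred", type = "character"),
    make_option("--annotations", type = "character"),
    make_option("--thresholds", type = "character",
                default = "1e-15,1e-10,1e-5,1e-2"))), args = rest)
  need(op, "pred"); need(op, "annotations")
  run(print(enrichment_summary(
    read_complex_catalog(op$pred), read_annotations(op$annotations),
    thresholds = as.numeric(strsplit(op$thresholds, ",")[[1]]))))
} else if (cmd == "sweep") {
  op <- parse_args(OptionParser(option_list = c(opts_common, list(
    make_option("--ref", type = "character"),
    make_option("--alphas", type = "character", default = "0.8"),
    make_option("--lams", type = "character",
                default = "0.1,0.2,0.3,0.4,0.5,0.6,0.7,0.8,0.9"),
    make_option("--ovmaxes", type = "character", default = "0.8")))),
    args = rest)
  need(op, "ppi"); need(op, "expr"); need(op, "ref")
  run({
    sw <- parameter_sweep(op$ppi, op$expr, op$ref,
                          alpha = as.numeric(strsplit(op$alphas, ",")[[1]]),
                          lambda = as.numeric(strsplit(op$lams, ",")[[1]]),
                          ov_max = as.numeric(strsplit(op$ovmaxes, ",")[[1]]),
                          min_size = op$min_size)
    if (is.null(op$out)) print(sw) else
      write.table(sw, op$out, sep = "\t", quote = FALSE, row.names = FALSE)
  })
} else {
  usage_quit(sprintf("unknown command '%s'", cmd))
}
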