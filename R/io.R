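## Readers and writers for the plain-text formats the pipeline exchanges:
## PPI edge lists, expression matrices, complex catalogs, annotation maps,
## weighted-network dumps and module tables. All are tab-separated text.

#' Read a PPI network from a two-column edge-list TSV
#'
#' Lines starting with `#` are ignored. A third (confidence) column, if
#' present, is dropped with a warning since the pipeline derives its own
#' weights. Self-loops are dropped with a warning; duplicate and reversed
#' duplicate edges are collapsed.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple `igraph`.
#' @export
read_ppi_edges <- function(path) {
  if (!file.exists(path))
    stop(sprintf("PPI edge list not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0)
    stop(sprintf("no edges in %s", path), call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2))
    stop(sprintf("%s: line %d has fewer than two columns", path,
                 which(nf < 2)[1]), call. = FALSE)
  if (any(nf > 2))
    warning(sprintf("%s: extra columns beyond the two identifiers ignored",
                    path), call. = FALSE)
  u <- vapply(fields, `[[`, character(1), 1)
  v <- vapply(fields, `[[`, character(1), 2)
  loops <- u == v
  if (any(loops)) {
    warning(sprintf("%s: dropped %d self-loop(s)", path, sum(loops)),
            call. = FALSE)
    u <- u[!loops]; v <- v[!loops]
  }
  if (length(u) == 0)
    stop(sprintf("no usable edges in %s", path), call. = FALSE)
  g <- igraph::graph_from_edgelist(cbind(u, v), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read a gene expression matrix from TSV
#'
#' First column: gene identifier; remaining columns: numeric expression
#' values over conditions. A header row is auto-detected (second field of
#' the first line non-numeric). Rows with any blank or non-numeric value
#' are rejected, as are duplicate gene identifiers.
#'
#' @param path Path to the expression TSV.
#' @return Numeric matrix, one row per gene, rownames = gene identifiers.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path))
    stop(sprintf("expression matrix not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0)
    stop(sprintf("no rows in %s", path), call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first_val <- suppressWarnings(as.numeric(fields[[1]][2]))
  if (is.na(first_val)) {
    fields <- fields[-1]  # header row
    if (length(fields) == 0)
      stop(sprintf("only a header row in %s", path), call. = FALSE)
  }
  nf <- lengths(fields)
  if (length(unique(nf)) != 1)
    stop(sprintf("%s: ragged rows (column counts %s)", path,
                 paste(unique(nf), collapse = ", ")), call. = FALSE)
  if (nf[1] < 2)
    stop(sprintf("%s: need a gene id plus >= 1 expression column", path),
         call. = FALSE)
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate gene id '%s'", path,
                 ids[duplicated(ids)][1]), call. = FALSE)
  vals <- matrix(suppressWarnings(as.numeric(unlist(lapply(fields, `[`, -1)))),
                 nrow = length(fields), byrow = TRUE)
  bad <- apply(vals, 1, function(r) anyNA(r) | any(!is.finite(r)))
  if (any(bad)) {
    warning(sprintf(
      "%s: rejected %d row(s) with blank/non-numeric values (first: '%s')",
      path, sum(bad), ids[bad][1]), call. = FALSE)
    vals <- vals[!bad, , drop = FALSE]
    ids <- ids[!bad]
  }
  if (nrow(vals) == 0)
    stop(sprintf("%s: no complete expression rows", path), call. = FALSE)
  rownames(vals) <- ids
  colnames(vals) <- paste0("C", seq_len(ncol(vals)))
  vals
}

#' Read a reference complex catalog
#'
#' One complex per line, tab-separated member identifiers. Duplicate
#' members within a complex and duplicate complexes are collapsed. Files
#' written by [write_modules()] are recognized by their three leading
#' metadata columns (id, size, weight) and re-read as plain catalogs.
#'
#' @param path Path to the catalog TSV.
#' @return List of character vectors (one sorted member set per complex).
#' @export
read_complex_catalog <- function(path) {
  if (!file.exists(path))
    stop(sprintf("complex catalog not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # module-table dialect: id, size, weight, members... on every line, with
  # the size field equal to the member count
  is_module_table <- all(vapply(fields, function(f) {
    length(f) >= 4 &&
      !is.na(suppressWarnings(as.integer(f[2]))) &&
      suppressWarnings(as.integer(f[2])) == length(f) - 3L &&
      !is.na(suppressWarnings(as.numeric(f[3])))
  }, logical(1)))
  if (is_module_table) fields <- lapply(fields, function(f) f[-(1:3)])
  sets <- lapply(fields, function(f) sort(unique(f[nzchar(f)])))
  sets <- sets[lengths(sets) > 0]
  unique(sets)
}

#' Write a complex catalog
#'
#' @param complexes List of character vectors.
#' @param path Output path.
#' @export
write_complex_catalog <- function(complexes, path) {
  lines <- vapply(complexes, function(s) paste(sort(unique(s)),
                                               collapse = "\t"),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a term-to-protein annotation map
#'
#' Format: `term_id <tab> protein_id [<tab> domain]`, one pair per line;
#' the optional third column tags the ontology domain (e.g. BP/MF/CC).
#'
#' @param path Path to the annotation TSV.
#' @param domain Optional domain tag to filter on (requires a third column).
#' @return Named list: term id -> character vector of proteins.
#' @export
read_annotations <- function(path, domain = NULL) {
  if (!file.exists(path))
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2))
    stop(sprintf("%s: every line needs term_id <tab> protein_id", path),
         call. = FALSE)
  term <- vapply(fields, `[[`, character(1), 1)
  prot <- vapply(fields, `[[`, character(1), 2)
  if (!is.null(domain)) {
    if (any(lengths(fields) < 3))
      stop("domain filtering requires a third (domain) column", call. = FALSE)
    dom <- vapply(fields, `[[`, character(1), 3)
    keep <- dom == domain
    term <- term[keep]; prot <- prot[keep]
  }
  lapply(split(prot, term), function(p) sort(unique(p)))
}

#' Write detected modules as a TSV table
#'
#' One module per line: `module_id`, `size`, `internal_weight_sum`, then the
#' tab-separated member identifiers. [read_complex_catalog()] recognizes
#' this dialect, so detector output can be re-read as a catalog.
#'
#' @param x An `ectg` fit or a list of modules as returned by
#'   [detect_modules()].
#' @param path Output path.
#' @export
write_modules <- function(x, path) {
  df <- as.data.frame(x)
  lines <- sprintf("%s\t%d\t%.6g\t%s", df$module_id, df$size,
                   df$internal_weight, gsub(", ", "\t", df$members,
                                            fixed = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Export a weighted PPI network as TSV
#'
#' Columns: `u`, `v`, `omega`, `ptc`, `gec_raw`, `gec_used`.
#'
#' @param w A `weighted_ppi` object from [build_weighted_network()].
#' @param path Output path.
#' @export
write_weighted_network <- function(w, path) {
  stopifnot(inherits(w, "weighted_ppi"))
  utils::write.table(w$edges[, c("u", "v", "omega", "ptc", "gec_raw",
                                 "gec_used")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param expr Numeric matrix with gene rownames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  lines <- c(paste(c("gene", colnames(expr)), collapse = "\t"),
             vapply(seq_len(nrow(expr)), function(i)
               paste(c(rownames(expr)[i],
                       format(expr[i, ], digits = 10, trim = TRUE,
                              scientific = FALSE)),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a PPI network as a two-column edge-list TSV
#'
#' @param g A PPI graph.
#' @param path Output path.
#' @export
write_ppi_edges <- function(g, path) {
  g <- as_ppi_graph(g)
  el <- igraph::as_edgelist(g)
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, c(2, 1)]
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}
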