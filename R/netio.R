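# Data model and file I/O: expression matrices, differential-expression
# tables, TOM networks, sample traits, gene sets and gene rankings.
#
# All tabular files are TSV (or CSV) with a header row; lines starting with
# '#' are treated as comments. Floats are written with 10 significant digits.

TOM_SYMMETRY_TOL <- 1e-10

#' Construct a validated expression matrix
#'
#' A genes-by-samples numeric matrix with unique, non-empty gene and sample
#' identifiers and all values finite.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids Optional identifier vectors; default to the
#'   dimnames of `values`.
#' @return The validated matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_coex("expression values must be a numeric matrix")
  }
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop_coex("expression matrix needs gene and sample identifiers")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop_coex("identifier lengths do not match matrix dimensions")
  }
  check_unique_ids(gene_ids, "gene")
  check_unique_ids(sample_ids, "sample")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_coex("non-finite expression value at gene '%s', sample '%s'",
              gene_ids[bad[1L]], sample_ids[bad[2L]])
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

check_unique_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) stop_coex("missing or empty %s id", what)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_coex("duplicate %s ids: %s", what, paste(dup, collapse = ", "))
  }
  invisible(ids)
}

#' Construct a validated differential-expression table
#'
#' @param gene_id Character vector of unique gene ids.
#' @param log2fc Finite log2 fold changes.
#' @param padj Adjusted p-values in \[0,1\]; `NA` is allowed and treated as
#'   1 (never differentially expressed) by [deg_genes()].
#' @return A data.frame with columns `gene_id`, `log2fc`, `padj`.
#' @export
dea_table <- function(gene_id, log2fc, padj) {
  gene_id <- as.character(gene_id)
  check_unique_ids(gene_id, "gene")
  log2fc <- as.numeric(log2fc)
  padj <- as.numeric(padj)
  if (length(log2fc) != length(gene_id) || length(padj) != length(gene_id)) {
    stop_coex("gene_id, log2fc and padj must have equal length")
  }
  if (!all(is.finite(log2fc))) stop_coex("non-finite log2fc values present")
  ok <- is.na(padj) | (padj >= 0 & padj <= 1)
  if (!all(ok)) stop_coex("padj outside [0,1] for: %s",
                          paste(gene_id[!ok], collapse = ", "))
  data.frame(gene_id = gene_id, log2fc = log2fc, padj = padj,
             stringsAsFactors = FALSE)
}

#' Genes called differentially expressed at an adjusted-p cutoff
#'
#' Missing adjusted p-values count as 1, so such genes are never DEGs.
#'
#' @param dea A [dea_table()].
#' @param alpha Adjusted p-value cutoff (default 0.05).
#' @return Character vector of gene ids.
#' @export
deg_genes <- function(dea, alpha = 0.05) {
  padj <- ifelse(is.na(dea$padj), 1, dea$padj)
  dea$gene_id[padj < alpha]
}

#' Construct a validated TOM network
#'
#' A symmetric weighted adjacency with entries in \[0,1\] and unit diagonal,
#' as produced by topological-overlap network construction.
#'
#' @param weights Square numeric matrix.
#' @param gene_ids Optional gene ids; default rownames.
#' @return The validated matrix with symmetric dimnames.
#' @export
tom_network <- function(weights, gene_ids = rownames(weights)) {
  if (!is.matrix(weights) || !is.numeric(weights) ||
      nrow(weights) != ncol(weights)) {
    stop_coex("TOM weights must be a square numeric matrix")
  }
  if (is.null(gene_ids)) stop_coex("TOM needs gene identifiers")
  gene_ids <- as.character(gene_ids)
  check_unique_ids(gene_ids, "gene")
  if (length(gene_ids) != nrow(weights)) {
    stop_coex("gene id count does not match TOM dimension")
  }
  if (!all(is.finite(weights))) stop_coex("non-finite TOM weights present")
  asym <- max(abs(weights - t(weights)))
  if (asym > TOM_SYMMETRY_TOL) {
    stop_coex("TOM is asymmetric (max |T - t(T)| = %.3g)", asym)
  }
  weights <- (weights + t(weights)) / 2
  if (any(weights < 0 | weights > 1)) stop_coex("TOM weights outside [0,1]")
  if (max(abs(diag(weights) - 1)) > TOM_SYMMETRY_TOL) {
    stop_coex("TOM diagonal must be exactly 1")
  }
  diag(weights) <- 1
  dimnames(weights) <- list(gene_ids, gene_ids)
  weights
}

#' Construct a validated long-format trait table
#'
#' @param sample_id,trait_name Character vectors.
#' @param value Numeric trait values; `NA` allowed.
#' @return data.frame with one row per (sample, trait); pairs must be unique.
#' @export
trait_table <- function(sample_id, trait_name, value) {
  df <- data.frame(sample_id = as.character(sample_id),
                   trait_name = as.character(trait_name),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  key <- paste(df$sample_id, df$trait_name, sep = "\r")
  if (anyDuplicated(key)) {
    stop_coex("duplicate (sample_id, trait_name) pairs in trait table")
  }
  df
}

#' Construct a named gene set
#'
#' @param name Set label used in reports.
#' @param gene_ids Character ids; duplicates are an error.
#' @return list with elements `name` and `gene_ids`, class `gene_set`.
#' @export
gene_set <- function(name, gene_ids) {
  gene_ids <- as.character(gene_ids)
  check_unique_ids(gene_ids, if (length(gene_ids)) "gene" else "gene")
  structure(list(name = name, gene_ids = gene_ids), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes>\n", x$name, length(x$gene_ids)))
  invisible(x)
}

# ---- readers -----------------------------------------------------------

#' Read an expression matrix from TSV/CSV
#'
#' First column holds gene ids, header row holds sample ids. Row and column
#' order are preserved from the file.
#'
#' @param path File path.
#' @param sep Field delimiter; sniffed (tab vs comma) when `NULL`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, sep = NULL) {
  df <- read_table_file(path, sep = sep)
  gene_ids <- as.character(df[[1L]])
  check_unique_ids(gene_ids, "gene")
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    x <- vals[[j]]
    if (!is.numeric(x)) {
      suppress <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(suppress) & !is.na(x))
      if (length(bad)) {
        stop_coex("non-numeric expression value '%s' at gene '%s', sample '%s'",
                  x[bad[1L]], gene_ids[bad[1L]], names(vals)[j])
      }
      vals[[j]] <- suppress
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  expression_matrix(m)
}

#' Write an expression matrix to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @param comments Optional comment lines written as `# ...` headers.
#' @export
write_expression <- function(x, path, comments = character()) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path, comments)
}

#' Read a differential-expression table
#'
#' Expects columns `gene_id`, `log2fc`, `padj` (extra columns ignored;
#' common aliases such as `log2FoldChange` are recognized). Missing adjusted
#' p-values are kept as `NA` and treated as 1 downstream.
#'
#' @inheritParams read_expression
#' @return A [dea_table()].
#' @export
read_dea <- function(path, sep = NULL) {
  df <- read_table_file(path, sep = sep)
  pick <- function(aliases) {
    hit <- intersect(aliases, names(df))
    if (!length(hit)) stop_coex("missing column (one of: %s) in %s",
                                paste(aliases, collapse = ", "), path)
    df[[hit[[1L]]]]
  }
  dea_table(pick(c("gene_id", "gene", "id")),
            pick(c("log2fc", "log2FoldChange", "logFC")),
            pick(c("padj", "adj.P.Val", "qvalue", "FDR")))
}

#' Write a differential-expression table to TSV
#' @inheritParams write_expression
#' @param dea A [dea_table()].
#' @export
write_dea <- function(dea, path, comments = character()) {
  write_tsv_file(dea, path, comments)
}

#' Read a TOM network, dense or sparse-triplet
#'
#' Dense: square table, first column gene ids, header = same ids. Triplet:
#' three columns (gene_a, gene_b, weight), each undirected edge stored once;
#' the dense matrix is symmetrized by construction over `universe` (or the
#' genes seen in the file), absent edges are 0 and the diagonal is 1.
#'
#' @param path File path.
#' @param format `"dense"` or `"triplet"`.
#' @param universe Optional gene universe for triplet input.
#' @inheritParams read_expression
#' @return A [tom_network()].
#' @export
read_tom <- function(path, format = c("dense", "triplet"), universe = NULL,
                     sep = NULL) {
  format <- match.arg(format)
  df <- read_table_file(path, sep = sep, header = (format == "dense"))
  if (format == "dense") {
    gene_ids <- as.character(df[[1L]])
    m <- as.matrix(df[-1L])
    mode(m) <- "numeric"
    rownames(m) <- gene_ids
    return(tom_network(m))
  }
  if (ncol(df) != 3L) stop_coex("triplet TOM must have 3 columns")
  a <- as.character(df[[1L]]); b <- as.character(df[[2L]])
  w <- as.numeric(df[[3L]])
  if (any(!is.finite(w)) || any(w < 0 | w > 1)) {
    stop_coex("triplet TOM weights must be finite and in [0,1]")
  }
  ids <- if (is.null(universe)) sort_canonical(unique(c(a, b))) else
    sort_canonical(as.character(universe))
  miss <- setdiff(c(a, b), ids)
  if (length(miss)) stop_coex("triplet genes outside universe: %s",
                              paste(unique(miss), collapse = ", "))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ia <- match(a, ids); ib <- match(b, ids)
  m[cbind(ia, ib)] <- w
  m[cbind(ib, ia)] <- w
  diag(m) <- 1
  tom_network(m)
}

#' Write a TOM network as dense TSV
#' @inheritParams write_expression
#' @param tom A [tom_network()].
#' @export
write_tom <- function(tom, path, comments = character()) {
  df <- data.frame(gene_id = rownames(tom), tom, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path, comments)
}

#' Read a long-format trait table
#'
#' Accepts either long format (`sample_id`, `trait_name`, `value`) or wide
#' format (first column sample id, one column per trait), which is melted.
#'
#' @inheritParams read_expression
#' @return A [trait_table()].
#' @export
read_traits <- function(path, sep = NULL) {
  df <- read_table_file(path, sep = sep)
  if (all(c("sample_id", "trait_name", "value") %in% names(df))) {
    return(trait_table(df$sample_id, df$trait_name, df$value))
  }
  samples <- as.character(df[[1L]])
  traits <- names(df)[-1L]
  trait_table(rep(samples, times = length(traits)),
              rep(traits, each = length(samples)),
              unlist(df[-1L], use.names = FALSE))
}

#' Write a trait table to TSV
#' @inheritParams write_expression
#' @param traits A [trait_table()].
#' @export
write_traits <- function(traits, path, comments = character()) {
  write_tsv_file(traits, path, comments)
}

#' Write a gene ranking to TSV
#'
#' Emits three columns: `gene_id`, `count`, `rank` (1-based position in the
#' sorted ranking).
#'
#' @param ranking A `gene_ranking` as returned by [critical_genes()] or
#'   [neighbor_genes()].
#' @inheritParams write_expression
#' @export
write_ranking <- function(ranking, path, comments = character()) {
  df <- data.frame(gene_id = ranking$gene_id, count = ranking$count,
                   rank = seq_len(nrow(ranking)), stringsAsFactors = FALSE)
  write_tsv_file(df, path, comments)
}

#' Read a gene ranking written by [write_ranking()]
#' @inheritParams read_expression
#' @return data.frame of class `gene_ranking` (gene_id, count).
#' @export
read_ranking <- function(path, sep = NULL) {
  df <- read_table_file(path, sep = sep)
  new_gene_ranking(as.character(df$gene_id), as.integer(df$count),
                   kind = "file", params = list(path = path))
}

# ---- universe alignment ------------------------------------------------

gene_ids_of <- function(obj) {
  if (is.matrix(obj)) rownames(obj)
  else if (inherits(obj, "gene_set")) obj$gene_ids
  else if (is.data.frame(obj) && "gene_id" %in% names(obj)) obj$gene_id
  else stop_coex("cannot extract gene ids from object of class %s",
                 paste(class(obj), collapse = "/"))
}

restrict_to <- function(obj, universe) {
  if (is.matrix(obj)) {
    if (nrow(obj) == ncol(obj) && identical(rownames(obj), colnames(obj))) {
      obj[universe, universe, drop = FALSE]
    } else {
      obj[universe, , drop = FALSE]
    }
  } else if (inherits(obj, "gene_set")) {
    gene_set(obj$name, intersect(universe, obj$gene_ids))
  } else {
    obj[match(universe, obj$gene_id), , drop = FALSE]
  }
}

#' Restrict a collection of objects to a shared gene universe
#'
#' Every object is cut down to the intersection of all gene-id sets and
#' reindexed in the canonical (lexicographic) order. Gene sets are treated
#' as selections, not id carriers: they are restricted but do not shrink the
#' universe.
#'
#' @param ... Named objects carrying gene ids (expression matrices, TOM
#'   matrices, DEA tables, `gene_set`s).
#' @param gene_sets Optional named list of `gene_set` objects to restrict
#'   without contributing to the intersection.
#' @return list with `objects` (aligned, same names), `universe` (canonical
#'   id vector) and `dropped` (per-source ids removed).
#' @export
align_universe <- function(..., gene_sets = list()) {
  objs <- list(...)
  if (length(objs) == 1L && is.null(names(objs)) && is.list(objs[[1L]]) &&
      !is.data.frame(objs[[1L]])) {
    objs <- objs[[1L]]
  }
  if (length(objs) < 2L && !length(gene_sets)) {
    stop_coex("align_universe needs at least two objects")
  }
  if (is.null(names(objs)) || any(!nzchar(names(objs)))) {
    stop_coex("objects passed to align_universe must be named")
  }
  ids <- lapply(objs, gene_ids_of)
  universe <- Reduce(intersect, ids)
  if (!length(universe)) stop_coex("gene universes are disjoint")
  universe <- sort_canonical(universe)
  dropped <- lapply(ids, function(x) sort_canonical(setdiff(x, universe)))
  aligned <- lapply(objs, restrict_to, universe = universe)
  if (length(gene_sets)) {
    dropped_sets <- lapply(gene_sets, function(s)
      sort_canonical(setdiff(s$gene_ids, universe)))
    gene_sets <- lapply(gene_sets, restrict_to, universe = universe)
    dropped <- c(dropped, dropped_sets)
  }
  list(objects = aligned, gene_sets = gene_sets, universe = universe,
       dropped = dropped)
}
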