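# Co-expression network construction and module-level summaries: unsigned
# TOM, Louvain module detection, module eigengenes, trait binning,
# eigengene-trait correlation, and per-module ANOVA / DEG percentages.

#' Group assignment over a gene universe
#'
#' Common container for Louvain network modules and k-means embedding
#' clusters: a named integer vector of labels, relabelled contiguously
#' 0..n_groups-1 in order of decreasing group size (ties broken by the
#' lexicographically smallest member id).
#'
#' @param labels Named vector (names = gene ids) of group labels.
#' @return list with `labels` (named integer) and `n_groups`, class
#'   `gene_groups`.
#' @export
gene_groups <- function(labels) {
  if (is.null(names(labels))) stop_coex("group labels must be named by gene id")
  check_unique_ids(names(labels), "gene")
  first_gene <- vapply(split(names(labels), labels),
                       function(g) sort_canonical(g)[1L], character(1))
  sizes <- table(labels)
  ord <- order(-as.integer(sizes), first_gene[names(sizes)])
  new_label <- setNames(seq_along(ord) - 1L, names(sizes)[ord])
  out <- setNames(as.integer(new_label[as.character(labels)]), names(labels))
  structure(list(labels = out, n_groups = length(sizes)),
            class = "gene_groups")
}

#' @export
print.gene_groups <- function(x, ...) {
  cat(sprintf("<gene_groups: %d genes in %d groups>\n",
              length(x$labels), x$n_groups))
  invisible(x)
}

group_members <- function(groups, label) {
  names(groups$labels)[groups$labels == label]
}

#' Build an unsigned topological overlap matrix
#'
#' Adjacency is `a_ij = |cor(x_i, x_j)|^beta` (unsigned, soft threshold
#' `beta`); the topological overlap between genes i and j is
#' `(l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over third genes u and `k_i` the connectivity
#' `sum_u a_iu`. The diagonal is 1. High overlap means two genes share many
#' strong mutual neighbors, not merely a strong direct correlation.
#'
#' @param x Expression matrix (genes x samples, >= 3 samples).
#' @param beta Soft-power exponent, >= 1 (default 6, the common unsigned
#'   choice).
#' @return A [tom_network()].
#' @export
build_tom <- function(x, beta = 6) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 3L) stop_coex("build_tom needs >= 3 samples")
  if (beta < 1) stop_coex("beta must be >= 1")
  v <- apply(x, 1L, var)
  if (any(v == 0)) {
    stop_coex("zero-variance gene(s): %s",
              paste(rownames(x)[v == 0], collapse = ", "))
  }
  a <- abs(cor(t(x)))^beta
  diag(a) <- 0
  tom_from_adjacency(a, gene_ids = rownames(x))
}

# TOM from a precomputed adjacency (diagonal ignored); exposed for tests
# that evaluate the closed-form formula on hand-built graphs.
#' Topological overlap from an adjacency matrix
#'
#' @param a Symmetric adjacency in \[0,1\]; the diagonal is ignored.
#' @param gene_ids Optional ids, default rownames.
#' @return A [tom_network()].
#' @export
tom_from_adjacency <- function(a, gene_ids = rownames(a)) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  diag(a) <- 0
  if (any(a < 0 | a > 1)) stop_coex("adjacency weights must lie in [0,1]")
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  tom <- (tom + t(tom)) / 2
  tom_network(tom, gene_ids = gene_ids %||% as.character(seq_len(nrow(a))))
}

#' Louvain module detection on a TOM network
#'
#' Runs weighted Louvain community detection on the TOM graph (diagonal
#' removed). Deterministic for a fixed seed.
#'
#' @param tom A [tom_network()].
#' @param resolution Louvain resolution (default 1).
#' @param seed Integer seed (required: Louvain is stochastic).
#' @return A [gene_groups()] assignment.
#' @export
louvain_modules <- function(tom, resolution = 1, seed) {
  if (missing(seed)) stop_coex("louvain_modules requires an explicit seed")
  adj <- tom
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- setNames(igraph::membership(comm), rownames(tom))
  gene_groups(labels)
}

#' Modularity of a gene grouping on a TOM graph
#'
#' @param tom A [tom_network()].
#' @param groups A [gene_groups()].
#' @return Weighted Newman modularity.
#' @export
tom_modularity <- function(tom, groups) {
  adj <- tom
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  igraph::modularity(g, groups$labels[rownames(tom)] + 1L)
}

#' Module eigengene: first principal component of a gene group
#'
#' Genes are standardized across samples; the eigengene is the first right
#' singular vector of the standardized submatrix (one score per sample,
#' unit norm), oriented so that its mean correlation with the member genes
#' is non-negative.
#'
#' @param x Expression matrix.
#' @param genes A [gene_set()] or character vector of member ids (>= 2).
#' @return list with `scores` (named per sample), `loading` (named per
#'   gene, unit norm), `var_explained`, class `eigengene`.
#' @export
eigengene <- function(x, genes) {
  ids <- if (inherits(genes, "gene_set")) genes$gene_ids else as.character(genes)
  missing_ids <- setdiff(ids, rownames(x))
  if (length(missing_ids)) {
    stop_coex("genes absent from expression matrix: %s",
              paste(head(missing_ids, 5L), collapse = ", "))
  }
  if (length(ids) < 2L || ncol(x) < 2L) {
    stop_coex("eigengene needs >= 2 genes and >= 2 samples")
  }
  sub <- x[ids, , drop = FALSE]
  v <- apply(sub, 1L, var)
  if (all(v == 0)) stop_coex("all genes in the set are constant")
  if (any(v == 0)) {
    warning("dropping zero-variance genes: ",
            paste(ids[v == 0], collapse = ", "))
    sub <- sub[v > 0, , drop = FALSE]
  }
  z <- t(scale(t(sub)))
  sv <- svd(z, nu = 1L, nv = 1L)
  scores <- sv$v[, 1L]
  loading <- sv$u[, 1L]
  # orient: eigengene should track, not mirror, its member genes
  mean_cor <- mean(cor(scores, t(sub)))
  if (is.finite(mean_cor) && mean_cor < 0) {
    scores <- -scores
    loading <- -loading
  }
  structure(list(scores = setNames(scores, colnames(sub)),
                 loading = setNames(loading, rownames(sub)),
                 var_explained = sv$d[1L]^2 / sum(sv$d^2)),
            class = "eigengene")
}

#' Eigengene-trait Pearson correlation
#'
#' Pairwise-complete Pearson correlation between an eigengene's sample
#' scores and each trait; fewer than 3 complete pairs (or a constant trait)
#' yields a missing r rather than 0.
#'
#' @param eig An [eigengene()].
#' @param traits A [trait_table()].
#' @return data.frame with `trait_name`, `r`, `p`, `n_pairs`.
#' @export
module_trait_cor <- function(eig, traits) {
  do.call(rbind, lapply(split(traits, traits$trait_name), function(tr) {
    v <- setNames(tr$value, tr$sample_id)[names(eig$scores)]
    ok <- !is.na(v)
    n <- sum(ok)
    if (n < 3L || sd(v[ok]) == 0 || sd(eig$scores[ok]) == 0) {
      return(data.frame(trait_name = tr$trait_name[1L], r = NA_real_,
                        p = NA_real_, n_pairs = n))
    }
    ct <- stats::cor.test(eig$scores[ok], v[ok], method = "pearson")
    data.frame(trait_name = tr$trait_name[1L], r = unname(ct$estimate),
               p = ct$p.value, n_pairs = n)
  }))
}

#' Bin a trait into ordered classes
#'
#' Classes are left-closed, right-open intervals `[e_k, e_{k+1})`; the lowest
#' class is open below and the highest open above, so every observed value
#' falls in exactly one class. Three edges give the four-class groupings
#' used for alcohol traits (e.g. AUDIT edges 25, 50, 100).
#'
#' @param traits A [trait_table()].
#' @param trait_name Which trait to bin.
#' @param edges Strictly increasing numeric cut points.
#' @return list with `trait_name`, `edges`, `class` (named integer per
#'   sample, 1-based; `NA` for missing values), class `trait_binning`.
#' @export
bin_trait <- function(traits, trait_name, edges) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop_coex("bin edges must be strictly increasing")
  }
  tr <- traits[traits$trait_name == trait_name, , drop = FALSE]
  if (!nrow(tr)) stop_coex("trait '%s' not present", trait_name)
  cls <- findInterval(tr$value, edges) + 1L
  structure(list(trait_name = trait_name, edges = edges,
                 class = setNames(cls, tr$sample_id),
                 n_classes = length(edges) + 1L),
            class = "trait_binning")
}

#' Percentage of genes per group significant by one-way ANOVA
#'
#' For every gene, a one-way ANOVA of expression across the trait classes;
#' per group (module or cluster), the percentage of member genes with
#' p < alpha. Genes with zero between- and within-class variance are counted
#' as non-significant. Every class must hold at least 2 samples, otherwise
#' the computation aborts for that trait.
#'
#' @param x Expression matrix.
#' @param groups A [gene_groups()].
#' @param binning A [bin_trait()] result.
#' @param alpha Significance cutoff (default 0.05).
#' @return data.frame with `group`, `n_genes`, `pct_significant`.
#' @export
pct_significant_by_anova <- function(x, groups, binning, alpha = 0.05) {
  cls <- binning$class[colnames(x)]
  keep <- !is.na(cls)
  if (sum(keep) < 4L) stop_coex("too few samples with trait classes")
  cls <- cls[keep]
  counts <- table(cls)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop_coex("trait '%s': every class needs >= 2 samples (sizes: %s)",
              binning$trait_name, paste(counts, collapse = ", "))
  }
  p <- anova_pvalues(x[, keep, drop = FALSE], cls)
  sig <- p < alpha
  per_group(groups, function(members) 100 * mean(sig[members]))
}

# Vectorized one-way fixed-effects ANOVA over genes (rows).
# Degenerate genes (no within- and no between-class variance) get p = 1;
# perfect separation (between > 0, within = 0) gets p = 0.
anova_pvalues <- function(x, cls) {
  cls <- as.factor(cls)
  k <- nlevels(cls)
  n <- length(cls)
  gm <- rowMeans(x)
  ssb <- 0
  ssw <- 0
  for (lev in levels(cls)) {
    idx <- cls == lev
    mu <- rowMeans(x[, idx, drop = FALSE])
    ssb <- ssb + sum(idx) * (mu - gm)^2
    ssw <- ssw + rowSums((x[, idx, drop = FALSE] - mu)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  p[ssw == 0 & ssb > 0] <- 0
  setNames(p, rownames(x))
}

per_group <- function(groups, fn) {
  labs <- sort(unique(groups$labels))
  data.frame(group = labs,
             n_genes = vapply(labs, function(l)
               sum(groups$labels == l), integer(1)),
             value = vapply(labs, function(l)
               fn(group_members(groups, l)), numeric(1)))
}

#' Percentage of DEGs per group
#'
#' @param groups A [gene_groups()].
#' @param degs A [gene_set()] of DEGs; must be a subset of the grouped genes.
#' @return data.frame with `group`, `n_genes`, `value` (percentage).
#' @export
pct_deg <- function(groups, degs) {
  ids <- if (inherits(degs, "gene_set")) degs$gene_ids else as.character(degs)
  outside <- setdiff(ids, names(groups$labels))
  if (length(outside)) {
    stop_coex("DEGs outside the grouped universe: %s",
              paste(head(outside, 5L), collapse = ", "))
  }
  per_group(groups, function(members) 100 * mean(members %in% ids))
}
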