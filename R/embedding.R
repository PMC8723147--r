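# First-order graph embedding of the TOM with negative sampling, k-means
# clustering of the embedding, and module-vs-cluster quality checks.

#' Embed a TOM network into d-dimensional coordinates
#'
#' First-order, edge-sampling embedding with negative sampling: per epoch a
#' budget of `total_samples * n_genes` gene pairs is drawn uniformly (in
#' `n_batches` mini-batches) and each pair's coordinate dot product is pushed
#' toward its TOM weight (squared loss), so strongly overlapping genes are
#' pulled together in proportion to their weight; an additional
#' `negative_ratio` fraction of random pairs is pushed toward dot product 0.
#' The learning rate decays linearly from `learning_rate` to near 0 across
#' epochs, and each step is normalized by the mean squared coordinate row
#' norm (a curvature estimate for the quadratic loss), so the rate is
#' scale-invariant. Gene rows are sorted into canonical (lexicographic)
#' order before any sampling, so the result is invariant to the input row
#' order and deterministic given the seed.
#'
#' @param tom A [tom_network()] with at least one nonzero off-diagonal
#'   weight.
#' @param d Embedding dimension (>= 2; default 64).
#' @param max_epoch Number of epochs (default 100).
#' @param learning_rate Initial learning rate (default 0.1).
#' @param negative_ratio Negative pairs per positive pair (default 0.15).
#' @param total_samples Per-epoch sampling budget, in pairs per gene
#'   (default 75).
#' @param seed Integer seed (required).
#' @param n_batches Mini-batches per epoch (default 8).
#' @return genes x d numeric matrix, rows in canonical gene order, columns
#'   `dim1..dimd`.
#' @export
embed_network <- function(tom, d = 64L, max_epoch = 100L,
                          learning_rate = 0.1, negative_ratio = 0.15,
                          total_samples = 75, seed, n_batches = 8L) {
  if (missing(seed)) stop_coex("embed_network requires an explicit seed")
  if (d < 2L) stop_coex("embedding dimension must be >= 2")
  ord <- canonical_order(rownames(tom))
  tom <- tom[ord, ord, drop = FALSE]
  n <- nrow(tom)
  if (n < 2L) stop_coex("need >= 2 genes to embed")

  ut <- upper.tri(tom)
  w <- tom[ut]
  if (all(w == 0)) stop_coex("all off-diagonal weights are zero; nothing to embed")
  pair_i <- row(tom)[ut]
  pair_j <- col(tom)[ut]
  n_pairs <- length(w)

  set.seed(seed)
  emb <- matrix(runif(n * d, -0.5, 0.5) / sqrt(d), n, d)
  m_pos <- min(n_pairs, max(1L, ceiling(total_samples * n / n_batches)))
  m_neg <- max(1L, ceiling(negative_ratio * m_pos))

  for (epoch in seq_len(max_epoch)) {
    lr <- learning_rate * (1 - (epoch - 1) / max_epoch)
    # curvature of the squared dot-product loss scales with |e|^2
    msq <- mean(rowSums(emb^2))
    for (batch in seq_len(n_batches)) {
      sel <- sample.int(n_pairs, m_pos, replace = TRUE)
      neg <- sample.int(n_pairs, m_neg, replace = TRUE)
      ii <- c(pair_i[sel], pair_i[neg])
      jj <- c(pair_j[sel], pair_j[neg])
      target <- c(w[sel], numeric(m_neg))
      ei <- emb[ii, , drop = FALSE]
      ej <- emb[jj, , drop = FALSE]
      err <- rowSums(ei * ej) - target
      # mean gradient per touched node, then one normalized descent step
      node <- c(ii, jj)
      grad <- rowsum(rbind(ej, ei) * err, node)
      cnt <- tabulate(node, nbins = n)
      touched <- as.integer(rownames(grad))
      emb[touched, ] <- emb[touched, ] - (lr / msq) * grad / cnt[touched]
    }
  }
  dimnames(emb) <- list(rownames(tom), paste0("dim", seq_len(d)))
  emb
}

#' Write / read an embedding matrix as TSV
#'
#' @param emb genes x d matrix from [embed_network()].
#' @param path File path.
#' @param comments Optional `# ...` header lines.
#' @export
write_embedding <- function(emb, path, comments = character()) {
  df <- data.frame(gene_id = rownames(emb), emb, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path, comments)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- read_table_file(path)
  m <- as.matrix(df[-1L])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1L]])
  if (!all(is.finite(m))) stop_coex("non-finite embedding coordinates")
  m
}

#' Cluster an embedding with k-means
#'
#' Standard k-means (Hartigan-Wong) with `n_init` random restarts; the
#' restart with the lowest within-cluster sum of squares wins. Deterministic
#' given the seed.
#'
#' @param emb genes x d embedding matrix.
#' @param k Number of clusters (1 <= k <= n_genes).
#' @param seed Integer seed (required).
#' @param n_init Restarts (default 10).
#' @return A [gene_groups()] assignment.
#' @export
kmeans_clusters <- function(emb, k, seed, n_init = 10L) {
  if (missing(seed)) stop_coex("kmeans_clusters requires an explicit seed")
  if (k <= 0L) stop_coex("k must be positive")
  if (k > nrow(emb)) stop_coex("k exceeds the number of genes")
  if (k == nrow(emb)) {   # every gene its own cluster; WCSS is exactly 0
    return(gene_groups(setNames(seq_len(nrow(emb)), rownames(emb))))
  }
  set.seed(seed)
  km <- kmeans(emb, centers = k, nstart = n_init, iter.max = 100L)
  gene_groups(setNames(km$cluster, rownames(emb)))
}

#' Welch t comparison of a per-module vs per-cluster statistic
#'
#' Two-sided Welch t-test between two collections of group-level statistics
#' (e.g. percentage of ANOVA-significant genes per network module vs per
#' embedding cluster). If both collections have zero variance the p-value is
#' 1 when the means agree and 0 otherwise.
#'
#' @param stat_modules,stat_clusters Numeric vectors (>= 2 values each).
#' @return list with `t`, `p`, `mean_modules`, `mean_clusters`.
#' @export
compare_module_cluster_stats <- function(stat_modules, stat_clusters) {
  stat_modules <- stat_modules[is.finite(stat_modules)]
  stat_clusters <- stat_clusters[is.finite(stat_clusters)]
  if (length(stat_modules) < 2L || length(stat_clusters) < 2L) {
    stop_coex("need >= 2 finite values per side")
  }
  if (sd(stat_modules) == 0 && sd(stat_clusters) == 0) {
    same <- isTRUE(all.equal(mean(stat_modules), mean(stat_clusters)))
    return(list(t = if (same) 0 else Inf, p = if (same) 1 else 0,
                mean_modules = mean(stat_modules),
                mean_clusters = mean(stat_clusters)))
  }
  ht <- t.test(stat_modules, stat_clusters)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_modules = mean(stat_modules), mean_clusters = mean(stat_clusters))
}

#' Trait bin edges giving approximately equal class sizes
#'
#' Quartile cut points of the observed values, for the four-class groupings
#' used in trait ANOVA.
#'
#' @param traits A [trait_table()].
#' @param trait_name Trait to cut.
#' @return Numeric vector of 3 edges.
#' @export
quartile_edges <- function(traits, trait_name) {
  v <- traits$value[traits$trait_name == trait_name]
  v <- v[!is.na(v)]
  if (length(v) < 8L) stop_coex("too few values to form 4 classes")
  unname(quantile(v, c(0.25, 0.5, 0.75)))
}

#' Embedding quality report: do clusters preserve module-level biology?
#'
#' Compares network modules against embedding clusters on three axes:
#' (i) DEG concentration - the share of DEGs captured by the 3 clusters with
#' the highest DEG percentage; (ii) per-trait percentage of
#' ANOVA-significant genes, modules vs clusters (Welch t); (iii) per-trait
#' eigengene-trait |r|, modules vs clusters (Welch t). Large p-values mean
#' the embedding preserves the module-level trait structure.
#'
#' @param x Expression matrix.
#' @param modules,clusters [gene_groups()] assignments over the same genes.
#' @param degs A [gene_set()] of DEGs.
#' @param traits A [trait_table()].
#' @param trait_bins Named list of bin-edge vectors per trait; defaults to
#'   [quartile_edges()] for every trait present.
#' @param alpha ANOVA significance cutoff (default 0.05).
#' @return list with `deg_top3_share`, `deg_pct_modules`, `deg_pct_clusters`,
#'   and a data.frame `trait_tests` (trait, statistic, t, p).
#' @export
embedding_qc <- function(x, modules, clusters, degs, traits,
                         trait_bins = NULL, alpha = 0.05) {
  deg_mod <- pct_deg(modules, degs)
  deg_clu <- pct_deg(clusters, degs)
  ids <- if (inherits(degs, "gene_set")) degs$gene_ids else as.character(degs)
  top3 <- deg_clu$group[order(-deg_clu$value)][seq_len(min(3L, nrow(deg_clu)))]
  in_top3 <- names(clusters$labels)[clusters$labels %in% top3]
  deg_top3_share <- if (length(ids)) mean(ids %in% in_top3) else NA_real_

  trait_names <- unique(traits$trait_name)
  if (is.null(trait_bins)) {
    trait_bins <- lapply(setNames(trait_names, trait_names),
                         function(tn) quartile_edges(traits, tn))
  }
  rows <- list()
  for (tn in trait_names) {
    binning <- bin_trait(traits, tn, trait_bins[[tn]])
    pm <- pct_significant_by_anova(x, modules, binning, alpha)$value
    pc <- pct_significant_by_anova(x, clusters, binning, alpha)$value
    cmp <- compare_module_cluster_stats(pm, pc)
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tn, statistic = "pct_anova_significant", t = cmp$t, p = cmp$p)

    rm_ <- abs(group_trait_r(x, modules, traits, tn))
    rc_ <- abs(group_trait_r(x, clusters, traits, tn))
    cmp2 <- compare_module_cluster_stats(rm_, rc_)
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tn, statistic = "eigengene_trait_abs_r", t = cmp2$t, p = cmp2$p)
  }
  list(deg_top3_share = deg_top3_share,
       deg_pct_modules = deg_mod, deg_pct_clusters = deg_clu,
       trait_tests = do.call(rbind, rows))
}

# per-group eigengene-trait correlation for one trait
group_trait_r <- function(x, groups, traits, trait_name) {
  labs <- sort(unique(groups$labels))
  vapply(labs, function(l) {
    members <- group_members(groups, l)
    if (length(members) < 2L) return(NA_real_)
    eg <- eigengene(x, members)
    mt <- module_trait_cor(eg, traits)
    mt$r[mt$trait_name == trait_name]
  }, numeric(1))
}
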