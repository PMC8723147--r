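# Validation statistics: hypergeometric overlap tests between gene lists,
# gene-trait correlations, cross-list correlation comparisons, and
# cross-cohort correlation of gene lists.

#' Hypergeometric overlap test between two gene sets
#'
#' Exact upper-tail probability P(X >= k) of observing the overlap `k` or
#' more when `|a|` genes are drawn without replacement from a universe of
#' size N containing `|b|` successes.
#'
#' @param a,b [gene_set()]s (or character vectors), subsets of `universe`.
#' @param universe The gene universe ([gene_set()] or character vector).
#' @return list with `k`, `size_a`, `size_b`, `n_universe`,
#'   `overlap_genes`, `p` (upper tail), class `overlap_result`.
#' @export
overlap_test <- function(a, b, universe) {
  ga <- if (inherits(a, "gene_set")) a$gene_ids else as.character(a)
  gb <- if (inherits(b, "gene_set")) b$gene_ids else as.character(b)
  gu <- if (inherits(universe, "gene_set")) universe$gene_ids else
    as.character(universe)
  if (!length(gu)) stop_coex("empty universe")
  outside <- setdiff(c(ga, gb), gu)
  if (length(outside)) {
    stop_coex("genes outside the universe: %s",
              paste(head(outside, 5L), collapse = ", "))
  }
  k <- length(intersect(ga, gb))
  p <- phyper(k - 1L, length(gb), length(gu) - length(gb), length(ga),
              lower.tail = FALSE)
  structure(list(k = k, size_a = length(ga), size_b = length(gb),
                 n_universe = length(gu),
                 overlap_genes = sort_canonical(intersect(ga, gb)),
                 p = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap: %d of %d vs %d in N=%d, P(X>=k) = %.4g>\n",
              x$k, x$size_a, x$size_b, x$n_universe, x$p))
  invisible(x)
}

#' Per-gene, per-trait Pearson correlation
#'
#' Pairwise-complete Pearson correlation of each gene's expression with each
#' trait; constant genes or traits (or < 3 complete pairs) yield `NA`.
#'
#' @param x Expression matrix.
#' @param genes [gene_set()] or id vector.
#' @param traits A [trait_table()].
#' @return data.frame with `gene_id`, `trait_name`, `r`, `n_pairs`.
#' @export
gene_trait_cor <- function(x, genes, traits) {
  ids <- if (inherits(genes, "gene_set")) genes$gene_ids else
    as.character(genes)
  missing_ids <- setdiff(ids, rownames(x))
  if (length(missing_ids)) {
    stop_coex("genes absent from expression matrix: %s",
              paste(head(missing_ids, 5L), collapse = ", "))
  }
  out <- lapply(split(traits, traits$trait_name), function(tr) {
    v <- setNames(tr$value, tr$sample_id)[colnames(x)]
    ok <- !is.na(v)
    n <- sum(ok)
    if (n < 3L || sd(v[ok]) == 0) {
      r <- rep(NA_real_, length(ids))
    } else {
      r <- suppressWarnings(
        as.numeric(cor(t(x[ids, ok, drop = FALSE]), v[ok])))
      r[apply(x[ids, ok, drop = FALSE], 1L, sd) == 0] <- NA_real_
    }
    data.frame(gene_id = ids, trait_name = tr$trait_name[1L], r = r,
               n_pairs = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare |r| distributions across gene lists
#'
#' Per trait, tests whether the absolute gene-trait correlation coefficients
#' differ across gene lists: a two-sided Welch t-test for exactly 2 lists, a
#' one-way ANOVA with Tukey HSD post-hoc adjusted pairwise p-values for 3 or
#' more. Absolute values are used because the interest is the size of the
#' correlation, not its direction.
#'
#' @param cors Named list of [gene_trait_cor()] results, one per gene list.
#' @return data.frame with `trait_name`, `test`, `p`, and for >= 3 lists one
#'   row per Tukey pair (`comparison` column).
#' @export
compare_gene_lists_cor <- function(cors) {
  if (length(cors) < 2L) stop_coex("need >= 2 gene lists to compare")
  if (is.null(names(cors))) names(cors) <- paste0("list", seq_along(cors))
  long <- do.call(rbind, lapply(names(cors), function(nm) {
    df <- cors[[nm]]
    data.frame(list = nm, trait_name = df$trait_name, absr = abs(df$r),
               stringsAsFactors = FALSE)
  }))
  long <- long[is.finite(long$absr), , drop = FALSE]
  out <- lapply(split(long, long$trait_name), function(tr) {
    grp <- factor(tr$list)
    if (any(table(grp) < 3L)) stop_coex("need >= 3 |r| values per list")
    v <- tapply(tr$absr, grp, var)
    if (all(v == 0)) {
      m <- tapply(tr$absr, grp, mean)
      p <- if (max(m) - min(m) == 0) 1 else 0
      return(data.frame(trait_name = tr$trait_name[1L], test = "degenerate",
                        comparison = "all", p = p, stringsAsFactors = FALSE))
    }
    if (nlevels(grp) == 2L) {
      ht <- t.test(absr ~ grp, data = tr)
      return(data.frame(trait_name = tr$trait_name[1L], test = "welch_t",
                        comparison = paste(levels(grp), collapse = " vs "),
                        p = ht$p.value, stringsAsFactors = FALSE))
    }
    fit <- aov(absr ~ grp, data = tr)
    p_anova <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tk <- TukeyHSD(fit)$grp
    rbind(data.frame(trait_name = tr$trait_name[1L], test = "anova",
                     comparison = "all", p = p_anova,
                     stringsAsFactors = FALSE),
          data.frame(trait_name = tr$trait_name[1L], test = "tukey",
                     comparison = rownames(tk), p = tk[, "p adj"],
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-cohort correlation between two gene lists
#'
#' Pearson correlation matrix, in an independent cohort, between the top
#' `top_n` genes of each list, and the mean absolute coefficient - the
#' replication check that a candidate list co-expresses with the DEGs in a
#' dataset not used to derive it.
#'
#' @param x2 Expression matrix of the independent cohort.
#' @param list_a,list_b Gene id vectors or [gene_set()]s, already ordered by
#'   relevance (e.g. ranking count or |log2fc|); the first `top_n` present
#'   in `x2` are used.
#' @param top_n Genes kept per list (default 50).
#' @return list with `cor_matrix` (a-genes x b-genes), `mean_abs_r`,
#'   `genes_a`, `genes_b`.
#' @export
cross_cohort_cor <- function(x2, list_a, list_b, top_n = 50L) {
  pick <- function(l) {
    ids <- if (inherits(l, "gene_set")) l$gene_ids else as.character(l)
    ids <- ids[ids %in% rownames(x2)]
    head(ids, top_n)
  }
  ga <- pick(list_a)
  gb <- pick(list_b)
  if (length(ga) < 2L || length(gb) < 2L) {
    stop_coex("fewer than 2 usable genes in a list")
  }
  cm <- cor(t(x2[ga, , drop = FALSE]), t(x2[gb, , drop = FALSE]))
  list(cor_matrix = cm, mean_abs_r = mean(abs(cm)), genes_a = ga,
       genes_b = gb)
}
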