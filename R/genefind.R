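# Critical-gene and neighbor-gene identification: count impact genes near
# each gene, either by Euclidean distance in the classifier-selected
# embedding subspace (critical genes) or by TOM edge weight (neighbor
# genes), and rank genes by the count.

#' Proximity parameters for gene ranking
#'
#' @param sigma Explicit Euclidean distance cutoff, or `NULL` to use
#'   `sigma_percentile`.
#' @param sigma_percentile When `sigma` is `NULL`: sigma is this percentile
#'   of all gene-to-impact distances, resolved separately in each model's
#'   subspace (default 5).
#' @param epsilon TOM edge-weight cutoff in \[0,1\] for neighbor genes
#'   (default 0.1); weights must strictly exceed it, so 1 admits none.
#' @return list of class `proximity_params`.
#' @export
proximity_params <- function(sigma = NULL, sigma_percentile = 5,
                             epsilon = 0.1) {
  if (!is.null(sigma)) {
    if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) ||
        sigma < 0) {
      stop_coex("sigma must be a single number >= 0 (Inf allowed)")
    }
  } else {
    assert_scalar_number(sigma_percentile, "sigma_percentile")
    if (sigma_percentile <= 0 || sigma_percentile >= 100) {
      stop_coex("sigma_percentile must be in (0, 100)")
    }
  }
  assert_scalar_number(epsilon, "epsilon")
  if (epsilon < 0 || epsilon > 1) stop_coex("epsilon must be in [0, 1]")
  structure(list(sigma = sigma, sigma_percentile = sigma_percentile,
                 epsilon = epsilon), class = "proximity_params")
}

new_gene_ranking <- function(gene_id, count, kind, params = list()) {
  ord <- order(-count, gene_id, method = "radix")
  structure(data.frame(gene_id = gene_id[ord],
                       count = as.integer(count[ord]),
                       stringsAsFactors = FALSE),
            kind = kind, params = params,
            class = c("gene_ranking", "data.frame"))
}

#' Positive-count genes of a ranking
#' @param ranking A `gene_ranking`.
#' @return Character vector of genes with count >= 1.
#' @export
ranked_genes <- function(ranking) {
  ranking$gene_id[ranking$count >= 1L]
}

# squared Euclidean distances between rows of a and rows of b
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Critical genes: proximity to impact genes in the embedding subspaces
#'
#' For each model's top-dimension set the embedding is restricted to those
#' dimensions, the Euclidean distance from every gene to every impact gene
#' is computed, and the impact genes strictly within the distance cutoff are
#' counted (a gene never counts itself). Counts are summed across models and
#' genes are ranked by the total, ties broken lexicographically. Every gene
#' of the universe appears in the ranking, possibly with count 0.
#'
#' When no explicit `sigma` is given it is resolved per model subspace as
#' the `sigma_percentile`-th percentile of the pooled gene-to-impact
#' distances (self-pairs excluded), so the cutoff adapts to the geometry of
#' each subspace.
#'
#' @param emb genes x d embedding matrix.
#' @param impact A [gene_set()] (or character vector) of impact genes.
#' @param tops A single [select_top_dims()] result or a list of them, one
#'   per model.
#' @param params A [proximity_params()].
#' @return data.frame of class `gene_ranking` (gene_id, count), sorted by
#'   decreasing count; attribute `params` records the resolved sigmas.
#' @export
critical_genes <- function(emb, impact, tops, params = proximity_params()) {
  ids <- if (inherits(impact, "gene_set")) impact$gene_ids else
    as.character(impact)
  if (!length(ids)) stop_coex("impact set is empty")
  missing_ids <- setdiff(ids, rownames(emb))
  if (length(missing_ids)) {
    stop_coex("impact genes absent from embedding: %s",
              paste(head(missing_ids, 5L), collapse = ", "))
  }
  if (inherits(tops, "top_dimensions")) tops <- list(tops)
  if (!length(tops)) stop_coex("need top dimensions from at least one model")

  genes <- rownames(emb)
  impact_col <- match(ids, genes)
  self <- cbind(impact_col, seq_along(ids))          # (gene row, impact col)
  total <- setNames(integer(length(genes)), genes)
  sigmas <- numeric(0)
  for (top in tops) {
    if (!length(top$dims)) {
      warning(sprintf("model '%s' selected no dimensions; skipped",
                      top$model_kind %||% "?"))
      next
    }
    ek <- emb[, top$dims, drop = FALSE]
    dist_gi <- cross_dist(ek, ek[ids, , drop = FALSE])
    sigma <- params$sigma %||%
      unname(quantile(dist_gi[-((self[, 2L] - 1L) * length(genes) + self[, 1L])],
                      params$sigma_percentile / 100))
    within <- dist_gi < sigma
    within[self] <- FALSE                            # never count yourself
    total <- total + rowSums(within)
    sigmas <- c(sigmas, sigma)
  }
  new_gene_ranking(genes, total, kind = "critical",
                   params = list(sigma = sigmas,
                                 sigma_percentile = params$sigma_percentile,
                                 n_models = length(tops)))
}

#' Neighbor genes: impact genes connected above a TOM weight cutoff
#'
#' For every gene, the number of impact genes j with `T[gene, j] > epsilon`
#' (strict inequality; the gene itself is excluded). The non-ML baseline for
#' critical genes.
#'
#' @param tom A [tom_network()].
#' @param impact A [gene_set()] or character vector of impact genes.
#' @param params A [proximity_params()] (only `epsilon` is used).
#' @return data.frame of class `gene_ranking`.
#' @export
neighbor_genes <- function(tom, impact, params = proximity_params()) {
  ids <- if (inherits(impact, "gene_set")) impact$gene_ids else
    as.character(impact)
  if (!length(ids)) stop_coex("impact set is empty")
  missing_ids <- setdiff(ids, rownames(tom))
  if (length(missing_ids)) {
    stop_coex("impact genes absent from TOM: %s",
              paste(head(missing_ids, 5L), collapse = ", "))
  }
  ti <- tom[, ids, drop = FALSE]
  ti[cbind(match(ids, rownames(tom)), seq_along(ids))] <- -Inf  # self
  counts <- rowSums(ti > params$epsilon)
  new_gene_ranking(rownames(tom), counts, kind = "neighbor",
                   params = list(epsilon = params$epsilon))
}

#' Choose epsilon so the neighbor list matches the critical list in size
#'
#' The target is the number of critical genes with a positive count. Since
#' the number of positive-count neighbor genes is a step function of
#' epsilon, the cutoff is picked from the observed per-gene maximum
#' gene-to-impact weights; when ties make the exact target unreachable the
#' nearest achievable size is used and flagged.
#'
#' @param tom A [tom_network()].
#' @param impact Impact [gene_set()] or id vector.
#' @param critical The critical `gene_ranking` whose size to match.
#' @return list with `epsilon`, `ranking` (neighbor `gene_ranking`),
#'   `target_size`, `achieved_size`, `exact` (logical).
#' @export
match_list_sizes <- function(tom, impact, critical) {
  ids <- if (inherits(impact, "gene_set")) impact$gene_ids else
    as.character(impact)
  target <- length(ranked_genes(critical))
  ti <- tom[, ids, drop = FALSE]
  ti[cbind(match(ids, rownames(tom)), seq_along(ids))] <- -Inf
  max_w <- apply(ti, 1L, max)                 # strongest impact link per gene
  if (target == 0L) {
    eps <- 1
  } else {
    # candidate cutoffs are the distinct observed link weights plus 0; the
    # positive-count size #(max_w > eps) is a step function, so scanning the
    # candidates finds the nearest achievable size (ties favor fewer genes)
    cand <- sort(unique(c(0, max_w[is.finite(max_w) & max_w >= 0])))
    sizes <- vapply(cand, function(e) sum(max_w > e), integer(1))
    gap <- abs(sizes - target)
    best <- which(gap == min(gap))
    best <- best[which.min(sizes[best])]
    eps <- cand[best]
  }
  params <- proximity_params(epsilon = eps)
  ranking <- neighbor_genes(tom, impact, params)
  achieved <- length(ranked_genes(ranking))
  if (achieved != target) {
    warning(sprintf("exact size match unreachable: target %d, achieved %d",
                    target, achieved))
  }
  list(epsilon = params$epsilon, ranking = ranking, target_size = target,
       achieved_size = achieved, exact = achieved == target)
}
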