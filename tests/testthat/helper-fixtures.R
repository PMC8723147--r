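# Shared fixtures and independent oracles for the test suite. The synthetic
# cohort is computed lazily once and reused across test files.

synth_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$fx)) {
      cfg <- synth_config(n_genes = 400L, n_samples_per_group = 40L,
                          n_modules = 4L, n_deg = 32L,
                          n_planted_regulators = 10L,
                          trait_module_map = c(audit = 1L,
                                               drinks_per_day = 2L),
                          seed = 101L)
      syn <- synth_generate(cfg)
      tom <- build_tom(syn$expression, beta = 6)
      modules <- louvain_modules(tom, resolution = 1, seed = 3L)
      emb <- embed_network(tom, d = 16L, max_epoch = 50L, seed = 5L)
      cache$fx <- list(cfg = cfg, syn = syn, tom = tom, modules = modules,
                       emb = emb)
    }
    cache$fx
  }
})

# adjusted Rand index between two labelings (named or aligned vectors)
adjusted_rand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# brute-force double-loop critical-gene counts (oracle for critical_genes)
brute_critical <- function(emb, impact_ids, dims_list, sigma) {
  genes <- rownames(emb)
  counts <- setNames(integer(length(genes)), genes)
  for (dims in dims_list) {
    for (g in genes) {
      for (i in impact_ids) {
        if (g == i) next
        dist_gi <- sqrt(sum((emb[g, dims] - emb[i, dims])^2))
        if (dist_gi < sigma) counts[g] <- counts[g] + 1L
      }
    }
  }
  counts
}

# brute-force double-loop neighbor-gene counts (oracle for neighbor_genes)
brute_neighbor <- function(tom, impact_ids, epsilon) {
  genes <- rownames(tom)
  counts <- setNames(integer(length(genes)), genes)
  for (g in genes) {
    for (i in impact_ids) {
      if (g == i) next
      if (tom[g, i] > epsilon) counts[g] <- counts[g] + 1L
    }
  }
  counts
}

# exact hypergeometric upper tail by combinatorial enumeration; for N <= 30
# every term C(K, i) * C(N-K, n-i) and the denominator C(N, n) are integers
# below 2^53, so double arithmetic is exact
exact_hyper_upper <- function(k, K, N, n) {
  i <- seq(max(k, 0L), min(K, n))
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# build a tiny TOM-like matrix from an edge list (values in [0,1], diag 1)
toy_tom <- function(n, edges, ids = sprintf("g%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (e in edges) {
    m[e[[1L]], e[[2L]]] <- e[[3L]]
    m[e[[2L]], e[[1L]]] <- e[[3L]]
  }
  diag(m) <- 1
  m
}

# fabricate a model_results object from explicit importance vectors
fake_results <- function(model_kind, importances, accuracy = 0.9) {
  structure(lapply(seq_along(importances), function(i) {
    imp <- importances[[i]]
    if (is.null(names(imp))) names(imp) <- paste0("dim", seq_along(imp))
    list(model_kind = model_kind, repeat_index = i, seed = i,
         accuracy = accuracy, importance = imp / sum(imp))
  }), class = "model_results")
}

# embedding-like matrix whose class is the sign of dim1, for classifier tests
make_separable <- function(n = 200L, d = 8L, seed = 21L) {
  set.seed(seed)
  emb <- matrix(rnorm(n * d), n, d,
                dimnames = list(sprintf("g%03d", 1:n), paste0("dim", 1:d)))
  pos <- emb[, 1L] > 0
  if (mean(pos) > 0.5) pos <- !pos   # impact must be the minority class
  fc <- ifelse(pos, 1, 0.01) * runif(n, 0.9, 1.1)
  dea <- dea_table(rownames(emb), fc, rep(0.5, n))
  lab <- label_impact(dea, percentile = 100 * mean(pos))
  list(emb = emb, labels = lab,
       balanced = balance_downsample(lab, seed = seed))
}

fake_top <- function(dims, model_kind = "oracle") {
  structure(list(model_kind = model_kind, dims = as.integer(dims),
                 dim_names = paste0("dim", dims),
                 cumulative_importance = 1, cutoff = 0.5),
            class = "top_dimensions")
}
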