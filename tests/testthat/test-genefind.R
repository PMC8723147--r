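test_that("critical counting matches hand enumeration on a 1-D example", {
  emb <- matrix(c(0.0, 0.5, 2.0, 0.9), 4, 1,
                dimnames = list(c("A", "B", "C", "D"), "dim1"))
  rk <- critical_genes(emb, "A", fake_top(1L),
                       proximity_params(sigma = 1.0))
  expect_identical(rk$gene_id, c("B", "D", "A", "C"))
  expect_identical(rk$count, c(1L, 1L, 0L, 0L))
})

test_that("sigma extremes saturate and empty the counts", {
  fx <- synth_fixture()
  emb <- fx$emb[1:30, ]
  impact <- rownames(emb)[c(3, 10, 20)]
  tops <- list(fake_top(1:4, "a"), fake_top(5:8, "b"))

  rk_inf <- critical_genes(emb, impact, tops, proximity_params(sigma = Inf))
  expected <- ifelse(rownames(emb) %in% impact, 2L * 2L, 2L * 3L)
  expect_identical(setNames(rk_inf$count[match(rownames(emb), rk_inf$gene_id)],
                            rownames(emb)),
                   setNames(as.integer(expected), rownames(emb)))

  rk_0 <- critical_genes(emb, impact, tops, proximity_params(sigma = 0))
  expect_true(all(rk_0$count == 0L))
  expect_error(critical_genes(emb, character(0), tops), "empty")
})

test_that("neighbor counting matches hand enumeration and epsilon extremes", {
  tom <- toy_tom(3, list(list("g01", "g02", 0.3), list("g01", "g03", 0.1)),
                 ids = c("g01", "g02", "g03"))
  rk <- neighbor_genes(tom, "g01", proximity_params(epsilon = 0.2))
  expect_identical(rk$gene_id, c("g02", "g01", "g03"))
  expect_identical(rk$count, c(1L, 0L, 0L))

  rk1 <- neighbor_genes(tom, "g01", proximity_params(epsilon = 1))
  expect_true(all(rk1$count == 0L))

  rk0 <- neighbor_genes(tom, "g01", proximity_params(epsilon = 0))
  counts0 <- setNames(rk0$count, rk0$gene_id)
  expect_identical(counts0[["g02"]], 1L)  # nonzero link to impact
  expect_identical(counts0[["g03"]], 1L)
  expect_identical(counts0[["g01"]], 0L)  # self excluded
})

test_that("both rankings equal brute-force enumeration on random instances", {
  for (rep in 1:6) {
    set.seed(500 + rep)
    n <- sample(10:50, 1)
    d <- sample(3:6, 1)
    emb <- matrix(rnorm(n * d), n, d,
                  dimnames = list(sprintf("g%02d", 1:n), paste0("dim", 1:d)))
    impact <- sample(rownames(emb), sample(2:5, 1))
    dims_list <- list(sample(d, 2), sample(d, 2))
    sigma <- runif(1, 0.5, 3)
    tops <- lapply(dims_list, fake_top)
    rk <- critical_genes(emb, impact, tops, proximity_params(sigma = sigma))
    oracle <- brute_critical(emb, impact, dims_list, sigma)
    expect_identical(setNames(rk$count, rk$gene_id)[names(oracle)], oracle)

    w <- matrix(runif(n * n), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 1
    dimnames(w) <- dimnames(emb)[c(1, 1)]
    eps <- runif(1)
    rkn <- neighbor_genes(w, impact, proximity_params(epsilon = eps))
    oracle_n <- brute_neighbor(w, impact, eps)
    expect_identical(setNames(rkn$count, rkn$gene_id)[names(oracle_n)],
                     oracle_n)
  }
})

test_that("counts are monotone in the cutoffs", {
  fx <- synth_fixture()
  emb <- fx$emb[1:40, ]
  tom <- fx$tom[1:40, 1:40]
  impact <- rownames(emb)[c(1, 7, 25)]
  top <- fake_top(1:6)

  prev <- rep(-1L, 40)
  for (sigma in c(0, 0.05, 0.2, 0.5, 2)) {
    rk <- critical_genes(emb, impact, top, proximity_params(sigma = sigma))
    cnt <- setNames(rk$count, rk$gene_id)[rownames(emb)]
    expect_true(all(cnt >= prev))
    prev <- cnt
  }
  prev <- rep(.Machine$integer.max, 40)
  for (eps in c(0, 0.02, 0.1, 0.5, 1)) {
    rk <- neighbor_genes(tom, impact, proximity_params(epsilon = eps))
    cnt <- setNames(rk$count, rk$gene_id)[rownames(tom)]
    expect_true(all(cnt <= prev))
    prev <- cnt
  }
})

test_that("percentile sigma rule resolves per model subspace", {
  fx <- synth_fixture()
  emb <- fx$emb[1:50, ]
  impact <- rownames(emb)[1:5]
  rk <- critical_genes(emb, impact, fake_top(1:8),
                       proximity_params(sigma_percentile = 5))
  sig <- attr(rk, "params")$sigma
  dists <- coexrank:::cross_dist(emb[, 1:8], emb[impact, 1:8])
  dists <- dists[-((1:5 - 1L) * 50L + 1:5)]   # drop self pairs
  expect_equal(sig, unname(quantile(dists, 0.05)))
})

test_that("size matching finds exact or nearest-achievable neighbor lists", {
  fx <- synth_fixture()
  tom <- fx$tom
  lab <- label_impact(fx$syn$dea, 8)
  tops <- fake_top(1:8)
  critical <- critical_genes(fx$emb, lab$impact_genes, tops)
  ms <- match_list_sizes(tom, lab$impact_genes, critical)
  expect_true(ms$exact)   # continuous weights: all distinct
  expect_identical(ms$achieved_size, ms$target_size)
  expect_identical(length(ranked_genes(ms$ranking)), ms$target_size)

  # brute-force sweep confirms no epsilon does better
  ids <- lab$impact_genes
  ti <- tom[, ids]
  ti[cbind(match(ids, rownames(tom)), seq_along(ids))] <- -Inf
  max_w <- apply(ti, 1, max)
  best <- min(abs(vapply(unique(c(0, max_w)),
                         function(e) sum(max_w > e), integer(1)) -
                    ms$target_size))
  expect_identical(abs(ms$achieved_size - ms$target_size), as.integer(best))

  # target 0: epsilon 1 admits nothing
  empty_rank <- coexrank:::new_gene_ranking(rownames(tom),
                                            integer(nrow(tom)), "critical")
  ms0 <- match_list_sizes(tom, lab$impact_genes, empty_rank)
  expect_identical(ms0$epsilon, 1)
  expect_length(ranked_genes(ms0$ranking), 0L)

  # duplicated weights force a jump over the target
  tom_tie <- toy_tom(4, list(list("g01", "g02", 0.5), list("g01", "g03", 0.5),
                             list("g01", "g04", 0.2)))
  one_rank <- coexrank:::new_gene_ranking(rownames(tom_tie), c(1L, 0L, 0L, 0L),
                                          "critical")
  expect_warning(ms_tie <- match_list_sizes(tom_tie, "g01", one_rank),
                 "unreachable")
  expect_false(ms_tie$exact)
  expect_identical(ms_tie$target_size, 1L)
})

test_that("rankings break count ties lexicographically and cover the universe", {
  fx <- synth_fixture()
  lab <- label_impact(fx$syn$dea, 8)
  rk <- critical_genes(fx$emb, lab$impact_genes, fake_top(1:16))
  expect_identical(sort(rk$gene_id), rownames(fx$emb))
  expect_true(all(diff(rk$count) <= 0))
  ties <- split(rk$gene_id, rk$count)
  for (grp in ties) expect_identical(grp, sort(grp))
})
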