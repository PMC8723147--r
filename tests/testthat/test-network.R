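test_that("topological overlap matches its closed form on hand-built graphs", {
  # two genes joined with full weight: TOM = (0 + 1) / (1 + 1 - 1) = 1
  a <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("g1", "g2"),
                                                   c("g1", "g2")))
  tom <- tom_from_adjacency(a)
  expect_equal(tom["g1", "g2"], 1)

  # pair with no shared neighbors: overlap reduces to the direct weight
  a3 <- toy_tom(3, list(list("g01", "g02", 0.3)))
  diag(a3) <- 0
  tom3 <- tom_from_adjacency(a3)
  expect_equal(tom3["g01", "g02"], 0.3 / (0.3 + 1 - 0.3))

  # shared-neighbor term: l_12 = a13 * a32
  a4 <- toy_tom(3, list(list("g01", "g02", 0.2), list("g01", "g03", 0.5),
                        list("g02", "g03", 0.4)))
  diag(a4) <- 0
  tom4 <- tom_from_adjacency(a4)
  k <- rowSums(a4)
  expect_equal(tom4["g01", "g02"],
               (0.5 * 0.4 + 0.2) / (min(k[1], k[2]) + 1 - 0.2),
               ignore_attr = TRUE)
})

test_that("build_tom output is a valid TOM and permutation-equivariant", {
  fx <- synth_fixture()
  x <- fx$syn$expression[1:40, ]
  tom <- build_tom(x, beta = 6)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_equal(max(abs(tom - t(tom))), 0)
  expect_identical(unname(diag(tom)), rep(1, nrow(tom)))

  perm <- sample(nrow(x))
  tom_p <- build_tom(x[perm, ], beta = 6)
  expect_equal(tom_p, tom[perm, perm])

  xz <- rbind(x, flatgene = rep(3, ncol(x)))
  expect_error(build_tom(xz, beta = 6), "flatgene")
})

test_that("louvain separates disconnected cliques and is seed-stable", {
  edges <- c(lapply(combn(1:5, 2, simplify = FALSE),
                    function(p) list(p[1], p[2], 1)),
             lapply(combn(6:10, 2, simplify = FALSE),
                    function(p) list(p[1], p[2], 1)))
  tom <- toy_tom(10, edges)
  mod <- louvain_modules(tom, resolution = 1, seed = 1L)
  expect_identical(mod$n_groups, 2L)
  expect_length(unique(mod$labels[1:5]), 1L)
  expect_length(unique(mod$labels[6:10]), 1L)
  expect_false(mod$labels[1] == mod$labels[6])

  mod2 <- louvain_modules(tom, resolution = 1, seed = 1L)
  expect_identical(mod$labels, mod2$labels)

  # uniform weights: no community structure, modularity near zero
  u <- matrix(0.5, 8, 8, dimnames = list(paste0("g", 1:8), paste0("g", 1:8)))
  diag(u) <- 1
  modu <- louvain_modules(u, resolution = 1, seed = 1L)
  expect_lte(abs(tom_modularity(u, modu)), 0.05)
})

test_that("louvain beats the all-singletons partition on structured data", {
  fx <- synth_fixture()
  singletons <- gene_groups(setNames(seq_len(nrow(fx$tom)),
                                     rownames(fx$tom)))
  expect_gt(tom_modularity(fx$tom, fx$modules),
            tom_modularity(fx$tom, singletons))
  expect_gte(adjusted_rand(fx$modules$labels, fx$syn$truth$module_of), 0.7)
})

test_that("eigengene is the oriented first PC of the module", {
  x <- expression_matrix(rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8)),
                         sample_ids = paste0("s", 1:4))
  eg <- eigengene(x, c("g1", "g2"))
  expect_equal(abs(cor(eg$scores, x["g1", ])), 1, tolerance = 1e-12)
  expect_gt(cor(eg$scores, x["g1", ]), 0)   # oriented with members
  expect_equal(sum(eg$loading^2), 1, tolerance = 1e-12)

  # flipping the data flips scores but not the size of trait correlations
  eg_f <- eigengene(-x, c("g1", "g2"))
  tr <- trait_table(paste0("s", 1:4), "t", c(1, 3, 2, 5))
  expect_equal(abs(module_trait_cor(eg, tr)$r),
               abs(module_trait_cor(eg_f, tr)$r), tolerance = 1e-12)

  expect_error(eigengene(x, c("g1", "gX")), "gX")
})

test_that("eigengene of a planted module tracks its latent factor", {
  fx <- synth_fixture()
  members <- names(fx$syn$truth$module_of)[fx$syn$truth$module_of == 1L]
  eg <- eigengene(fx$syn$expression, members)
  f <- fx$syn$truth$factors[names(eg$scores), "module1"]
  expect_gte(abs(cor(eg$scores, f)), 0.9)
})

test_that("module_trait_cor handles perfect, mapped and degenerate traits", {
  fx <- synth_fixture()
  members <- names(fx$syn$truth$module_of)[fx$syn$truth$module_of == 1L]
  eg <- eigengene(fx$syn$expression, members)

  perfect <- trait_table(names(eg$scores), "self", eg$scores)
  expect_equal(module_trait_cor(eg, perfect)$r, 1, tolerance = 1e-12)

  const <- trait_table(names(eg$scores), "flat", rep(2, length(eg$scores)))
  expect_true(is.na(module_trait_cor(eg, const)$r))

  # the audit trait is generated from module 1: |r| beats other modules
  mt <- module_trait_cor(eg, fx$syn$traits)
  r_mapped <- abs(mt$r[mt$trait_name == "audit"])
  other_r <- vapply(2:4, function(m) {
    mem <- names(fx$syn$truth$module_of)[fx$syn$truth$module_of == m]
    eo <- eigengene(fx$syn$expression, mem)
    mo <- module_trait_cor(eo, fx$syn$traits)
    abs(mo$r[mo$trait_name == "audit"])
  }, numeric(1))
  expect_gt(r_mapped, median(other_r))
})

test_that("trait binning uses left-closed right-open intervals", {
  tr <- trait_table(paste0("s", 1:5), "audit", c(30, 25, 10, 100, 150))
  b <- bin_trait(tr, "audit", c(25, 50, 100))
  expect_identical(unname(b$class), c(2L, 2L, 1L, 4L, 4L))

  tr2 <- trait_table("s1", "drinking_years", 15)
  b2 <- bin_trait(tr2, "drinking_years", c(20, 30, 40))
  expect_identical(unname(b2$class), 1L)

  expect_error(bin_trait(tr, "audit", c(50, 25)), "increasing")
})

test_that("per-gene ANOVA percentages match oneway.test and edge cases", {
  fx <- synth_fixture()
  x <- fx$syn$expression
  b <- bin_trait(fx$syn$traits, "audit", quartile_edges(fx$syn$traits, "audit"))
  pct <- pct_significant_by_anova(x, fx$modules, b, alpha = 0.05)

  # cross-check the vectorized F against stats::oneway.test
  cls <- b$class[colnames(x)]
  p_vec <- coexrank:::anova_pvalues(x, cls)
  for (g in rownames(x)[c(2, 150, 388)]) {
    ow <- oneway.test(x[g, ] ~ factor(cls), var.equal = TRUE)
    expect_equal(unname(p_vec[g]), ow$p.value, tolerance = 1e-10)
  }

  # audit tracks module 1 (label ordering aside): the mapped module has the
  # highest share of significant genes
  mapped_label <- as.integer(names(which.max(table(
    fx$modules$labels[names(fx$syn$truth$module_of)[
      fx$syn$truth$module_of == 1L]]))))
  expect_identical(pct$group[which.max(pct$value)], mapped_label)

  expect_true(all(pct_significant_by_anova(x, fx$modules, b,
                                           alpha = 1)$value == 100))

  # constant genes are never significant
  xc <- expression_matrix(matrix(5, 4, ncol(x),
                                 dimnames = list(paste0("c", 1:4),
                                                 colnames(x))))
  gc <- gene_groups(setNames(c(0L, 0L, 1L, 1L), paste0("c", 1:4)))
  expect_true(all(pct_significant_by_anova(xc, gc, b)$value == 0))

  # a class with fewer than 2 samples aborts the trait
  b_bad <- b
  b_bad$class[] <- c(1L, rep(2L, length(b_bad$class) - 1L))
  expect_error(pct_significant_by_anova(x, fx$modules, b_bad), ">= 2 samples")
})

test_that("pct_deg counts per module and aggregates to the global rate", {
  g <- gene_groups(setNames(rep(0:1, each = 10), paste0("g", 1:20)))
  degs <- gene_set("deg", paste0("g", 1:3))
  pd <- pct_deg(g, degs)
  expect_identical(pd$value, c(30, 0))

  # full-module and empty DEG sets
  pd_full <- pct_deg(g, gene_set("deg", paste0("g", 11:20)))
  expect_identical(pd_full$value, c(0, 100))
  expect_true(all(pct_deg(g, gene_set("deg", character(0)))$value == 0))

  # size-weighted module percentages recover the global percentage
  fx <- synth_fixture()
  pd2 <- pct_deg(fx$modules, fx$syn$truth$deg_set)
  global <- 100 * length(fx$syn$truth$deg_set$gene_ids) /
    length(fx$modules$labels)
  expect_equal(sum(pd2$value * pd2$n_genes) / sum(pd2$n_genes), global)
})
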