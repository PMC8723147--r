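test_that("impact labeling takes the top percentile with ties included", {
  dea <- dea_table(sprintf("g%03d", 1:100), (1:100) / 100, rep(0.5, 100))
  lab <- label_impact(dea, percentile = 8)
  expect_identical(sort(lab$impact_genes), sprintf("g%03d", 93:100))

  # a distribution whose 92nd percentile is 0.1 yields threshold 0.1
  fc <- c(seq(0.001, 0.099, length.out = 46), 0.1,
          seq(0.12, 0.5, length.out = 4))   # 51 values, 92nd pctile = 0.1
  dea2 <- dea_table(sprintf("h%02d", seq_along(fc)), fc, rep(0.5, length(fc)))
  lab2 <- label_impact(dea2, percentile = 8)
  expect_equal(lab2$threshold, 0.1)
  expect_true(all(abs(dea2$log2fc[dea2$gene_id %in% lab2$impact_genes]) >= 0.1))

  # ties at the threshold are all included
  dea3 <- dea_table(paste0("t", 1:10), c(rep(0.1, 5), rep(0.9, 5)),
                    rep(0.5, 10))
  lab3 <- label_impact(dea3, percentile = 10)
  expect_setequal(lab3$impact_genes, paste0("t", 6:10))

  expect_error(label_impact(dea_table(c("a", "b"), c(0.2, 0.2), c(0.5, 0.5))),
               "identical")
})

test_that("downsampling balances classes uniformly at random", {
  dea <- dea_table(sprintf("g%03d", 1:100),
                   c(rep(1, 8), runif(92, 0, 0.5)), rep(0.5, 100))
  lab <- label_impact(dea, percentile = 8)
  expect_length(lab$impact_genes, 8L)
  bal <- balance_downsample(lab, seed = 3L)
  expect_length(bal, 16L)
  expect_identical(sum(lab$is_impact[bal]), 8L)
  expect_identical(balance_downsample(lab, seed = 3L), bal)

  # selection frequency of each non-impact gene matches the binomial rate
  non <- names(lab$is_impact)[!lab$is_impact]
  hits <- setNames(numeric(length(non)), non)
  n_rep <- 500L
  for (s in seq_len(n_rep)) {
    picked <- setdiff(balance_downsample(lab, seed = 1000L + s),
                      lab$impact_genes)
    hits[picked] <- hits[picked] + 1
  }
  p <- 8 / 92
  se <- sqrt(p * (1 - p) / n_rep)
  freq <- hits / n_rep
  expect_lt(abs(mean(freq) - p), se)            # overall rate on target
  expect_lt(max(abs(freq - p)), 4.5 * se)       # no gene is favored
})

test_that("classifiers find a perfectly separating dimension", {
  sep <- make_separable()
  res <- train_models(sep$emb, sep$balanced, sep$labels, seed = 31L)
  expect_length(res, 9L)                        # 3 kinds x 3 repeats
  acc <- accuracy_summary(res)
  tree_acc <- acc$mean_accuracy[acc$model_kind %in%
                                  c("random_forest", "xgboost")]
  expect_true(all(tree_acc >= 0.95))
  for (kind in c("random_forest", "xgboost", "logistic")) {
    imp <- coexrank:::mean_importance(res, kind)
    expect_identical(names(which.max(imp)), "dim1")
  }
  # importance vectors are nonnegative and sum to one for every fit
  for (r in res) {
    expect_true(all(r$importance >= 0))
    expect_equal(sum(r$importance), 1, tolerance = 1e-9)
  }
})

test_that("shuffled labels give chance-level accuracy", {
  sep <- make_separable()
  lab <- sep$labels
  set.seed(99)
  lab$is_impact[] <- sample(lab$is_impact)
  lab$impact_genes <- names(lab$is_impact)[lab$is_impact]
  res <- train_models(sep$emb, sep$balanced, lab, n_repeats = 10L,
                      seed = 41L, model_kinds = "random_forest")
  acc <- accuracy_summary(res)$mean_accuracy
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("top-dimension selection returns the minimal covering prefix", {
  res <- fake_results("logistic", list(c(0.4, 0.3, 0.2, 0.1)))
  top <- select_top_dims(res, "logistic", cutoff = 0.5)
  expect_identical(top$dims, c(1L, 2L))
  expect_equal(top$cumulative_importance, 0.7)

  res1 <- fake_results("logistic", list(c(1, 0, 0, 0)))
  expect_identical(select_top_dims(res1, "logistic")$dims, 1L)

  res_u <- fake_results("xgboost", list(rep(1 / 64, 64)))
  expect_length(select_top_dims(res_u, "xgboost")$dims, 32L)

  # invariant to the order in which dimensions are listed
  imp <- c(dim1 = 0.1, dim2 = 0.5, dim3 = 0.25, dim4 = 0.15)
  res_a <- fake_results("logistic", list(imp))
  res_b <- fake_results("logistic", list(imp[c(3, 1, 4, 2)]))
  expect_identical(sort(select_top_dims(res_a, "logistic")$dim_names),
                   sort(select_top_dims(res_b, "logistic")$dim_names))

  # averaging across repeats happens before ranking
  res_m <- fake_results("logistic",
                        list(c(0.6, 0.4, 0, 0), c(0, 0.4, 0.6, 0)))
  top_m <- select_top_dims(res_m, "logistic")
  expect_identical(top_m$dims[1L], 2L)          # dim2 has the highest mean
})

test_that("retraining on top dimensions preserves accuracy when they carry the signal", {
  sep <- make_separable()
  full <- train_models(sep$emb, sep$balanced, sep$labels, seed = 31L,
                       model_kinds = "random_forest")
  rt <- retrain_on_top_dims(sep$emb, sep$balanced, sep$labels,
                            fake_top(1L, "random_forest"), seed = 31L,
                            full = full)
  expect_gte(rt$ratio, 0.95)

  rt_all <- retrain_on_top_dims(sep$emb, sep$balanced, sep$labels,
                                fake_top(1:8, "random_forest"), seed = 31L,
                                full = full)
  expect_lt(abs(rt_all$ratio - 1), 0.1)

  rt_noise <- retrain_on_top_dims(sep$emb, sep$balanced, sep$labels,
                                  fake_top(5L, "random_forest"), seed = 31L,
                                  full = full)
  expect_lt(rt_noise$ratio, 0.8)
})
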