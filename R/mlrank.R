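# Impact-gene labeling, class balancing, explainable classifiers on the
# embedding coordinates, per-dimension importance, and top-dimension
# selection with a retrain check.

MODEL_KINDS <- c("logistic", "random_forest", "xgboost")

#' Label impact genes by top-percentile |log2 fold change|
#'
#' A gene is an impact gene when its |log2fc| reaches the
#' (100 - percentile)-th percentile of all |log2fc| values; ties at the
#' threshold are all included, so the set can slightly exceed the nominal
#' percentage. With the default 8 this is the "top 8 percent of differential
#' expression" rule used to anchor proximity counting.
#'
#' @param dea A [dea_table()].
#' @param percentile Percentage of genes to label impact (0 < p < 100).
#' @return list with `impact_genes`, `is_impact` (named logical),
#'   `threshold`, `percentile`, class `impact_labeling`.
#' @export
label_impact <- function(dea, percentile = 8) {
  if (percentile <= 0 || percentile >= 100) {
    stop_coex("percentile must be in (0, 100)")
  }
  afc <- abs(dea$log2fc)
  if (max(afc) == min(afc)) {
    stop_coex("all |log2fc| identical; impact labeling impossible")
  }
  threshold <- unname(quantile(afc, 1 - percentile / 100))
  is_impact <- setNames(afc >= threshold, dea$gene_id)
  structure(list(impact_genes = dea$gene_id[is_impact],
                 is_impact = is_impact,
                 threshold = threshold, percentile = percentile),
            class = "impact_labeling")
}

#' @export
print.impact_labeling <- function(x, ...) {
  cat(sprintf("<impact_labeling: %d/%d impact (top %.3g%%), |log2fc| >= %.4g>\n",
              sum(x$is_impact), length(x$is_impact), x$percentile, x$threshold))
  invisible(x)
}

#' Downsample non-impact genes to balance the classes
#'
#' Uniform sample without replacement of non-impact genes, matched in size
#' to the impact set.
#'
#' @param labels An [label_impact()] result.
#' @param seed Integer seed (required).
#' @return Character vector (canonical order) of impact plus sampled
#'   non-impact gene ids.
#' @export
balance_downsample <- function(labels, seed) {
  if (missing(seed)) stop_coex("balance_downsample requires an explicit seed")
  impact <- names(labels$is_impact)[labels$is_impact]
  non <- names(labels$is_impact)[!labels$is_impact]
  if (!length(impact) || !length(non)) stop_coex("both classes must be non-empty")
  if (length(non) < length(impact)) {
    stop_coex("fewer non-impact (%d) than impact (%d) genes",
              length(non), length(impact))
  }
  set.seed(seed)
  sort_canonical(c(impact, sample(non, length(impact))))
}

fit_one_model <- function(kind, xtr, ytr, xte, yte, fit_seed) {
  set.seed(fit_seed)
  d <- ncol(xtr)
  if (kind == "logistic") {
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2L, sd)
    sdv[sdv == 0] <- 1
    ztr <- scale(xtr, mu, sdv)
    zte <- scale(xte, mu, sdv)
    df <- data.frame(y = ytr, ztr)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial(),
                                control = list(maxit = 1000L)))
    prob <- suppressWarnings(
      predict(fit, newdata = data.frame(zte), type = "response"))
    pred <- prob > 0.5
    imp <- abs(coef(fit)[-1L])
    imp[is.na(imp)] <- 0
  } else if (kind == "random_forest") {
    fit <- randomForest::randomForest(x = xtr, y = factor(ytr))
    pred <- predict(fit, xte) == "TRUE"
    imp <- fit$importance[, "MeanDecreaseGini"]
  } else {
    dtr <- xgboost::xgb.DMatrix(xtr, label = as.numeric(ytr))
    fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                            nthread = 1L),
                              data = dtr, nrounds = 100L, verbose = 0L)
    pred <- predict(fit, xgboost::xgb.DMatrix(xte)) > 0.5
    gain <- xgboost::xgb.importance(model = fit)
    imp <- setNames(numeric(d), colnames(xtr))
    imp[gain$Feature] <- gain$Gain
  }
  imp <- setNames(as.numeric(imp), colnames(xtr))
  s <- sum(imp)
  imp <- if (s > 0) imp / s else rep(1 / d, d)
  list(accuracy = mean(pred == yte), importance = imp)
}

stratified_split <- function(y, split_frac, seed) {
  set.seed(seed)
  train <- logical(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_tr <- max(1L, round(split_frac * length(idx)))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Train explainable classifiers on embedding coordinates
#'
#' For each model kind (logistic regression, random forest, gradient-boosted
#' trees) and each repeat: stratified `split_frac`/(1 - `split_frac`) split
#' of the balanced gene list, fit on the training fold, accuracy on the test
#' fold, and a per-dimension importance vector normalized to sum 1 (absolute
#' coefficients on standardized coordinates for the linear model,
#' impurity-based importance for the tree ensembles). A split that leaves a
#' single-class test fold is redrawn with the next seed. Tree-ensemble
#' hyperparameters stay at library defaults.
#'
#' @param emb genes x d embedding matrix.
#' @param balanced Gene ids from [balance_downsample()].
#' @param labels An [label_impact()] result.
#' @param split_frac Training fraction (default 0.8).
#' @param n_repeats Repeats per model kind (default 3).
#' @param seed Integer seed (required).
#' @param model_kinds Subset of `c("logistic", "random_forest", "xgboost")`.
#' @return list of per-fit results (`model_kind`, `repeat_index`,
#'   `accuracy`, `importance`), class `model_results`.
#' @export
train_models <- function(emb, balanced, labels, split_frac = 0.8,
                         n_repeats = 3L, seed, model_kinds = MODEL_KINDS) {
  if (missing(seed)) stop_coex("train_models requires an explicit seed")
  model_kinds <- match.arg(model_kinds, MODEL_KINDS, several.ok = TRUE)
  missing_ids <- setdiff(balanced, rownames(emb))
  if (length(missing_ids)) {
    stop_coex("balanced genes absent from embedding: %s",
              paste(head(missing_ids, 5L), collapse = ", "))
  }
  x <- emb[balanced, , drop = FALSE]
  y <- labels$is_impact[balanced]
  results <- list()
  for (r in seq_len(n_repeats)) {
    split_seed <- seed + 1000L * r
    repeat {
      train <- stratified_split(y, split_frac, split_seed)
      if (length(unique(y[!train])) == 2L && length(unique(y[train])) == 2L) break
      split_seed <- split_seed + 1L
    }
    for (kind in model_kinds) {
      fit <- fit_one_model(kind, x[train, , drop = FALSE], y[train],
                           x[!train, , drop = FALSE], y[!train],
                           fit_seed = split_seed + match(kind, MODEL_KINDS))
      results[[length(results) + 1L]] <- list(
        model_kind = kind, repeat_index = r, seed = split_seed,
        accuracy = fit$accuracy, importance = fit$importance)
    }
  }
  structure(results, class = "model_results")
}

#' Summarize model accuracies
#' @param results A [train_models()] result.
#' @return data.frame with per-kind mean and sd of test accuracy.
#' @export
accuracy_summary <- function(results) {
  kinds <- unique(vapply(results, `[[`, character(1), "model_kind"))
  do.call(rbind, lapply(kinds, function(k) {
    acc <- vapply(Filter(function(r) r$model_kind == k, results),
                  `[[`, numeric(1), "accuracy")
    data.frame(model_kind = k, mean_accuracy = mean(acc),
               sd_accuracy = if (length(acc) > 1L) sd(acc) else NA_real_,
               n_repeats = length(acc))
  }))
}

mean_importance <- function(results, model_kind) {
  keep <- Filter(function(r) r$model_kind == model_kind, results)
  if (!length(keep)) stop_coex("no results for model kind '%s'", model_kind)
  imp <- rowMeans(vapply(keep, `[[`, numeric(length(keep[[1L]]$importance)),
                         "importance"))
  setNames(imp, names(keep[[1L]]$importance))
}

#' Select the top embedding dimensions by cumulative importance
#'
#' Importance vectors are averaged over repeats for one model kind, sorted
#' in descending order (ties broken by dimension index), and the minimal
#' prefix whose cumulative importance reaches `cutoff` of the total is
#' returned.
#'
#' @param results A [train_models()] result.
#' @param model_kind Which model's importances to use.
#' @param cutoff Fraction of total importance to cover (default 0.5).
#' @return list with `model_kind`, `dims` (integer indices into the
#'   embedding columns), `dim_names`, `cumulative_importance`, class
#'   `top_dimensions`.
#' @export
select_top_dims <- function(results, model_kind, cutoff = 0.5) {
  imp <- mean_importance(results, model_kind)
  imp <- imp / sum(imp)
  ord <- order(-imp, seq_along(imp))
  cum <- cumsum(imp[ord])
  n_top <- which(cum >= cutoff)[1L]
  structure(list(model_kind = model_kind,
                 dims = ord[seq_len(n_top)],
                 dim_names = names(imp)[ord[seq_len(n_top)]],
                 cumulative_importance = unname(cum[n_top]),
                 cutoff = cutoff),
            class = "top_dimensions")
}

#' @export
print.top_dimensions <- function(x, ...) {
  cat(sprintf("<top_dimensions [%s]: %d dims, cumulative importance %.3f>\n",
              x$model_kind, length(x$dims), x$cumulative_importance))
  invisible(x)
}

#' Retrain on the top dimensions and compare accuracy
#'
#' Repeats the training protocol restricted to the selected dimensions and
#' reports the ratio of restricted to full mean test accuracy for that model
#' kind. A ratio near 1 means the selected subspace carries the signal the
#' model used.
#'
#' @inheritParams train_models
#' @param top A [select_top_dims()] result.
#' @param full Optional precomputed full-dimension [train_models()] result
#'   (saves refitting).
#' @return list with `model_kind`, `full_accuracy`, `restricted_accuracy`,
#'   `ratio`.
#' @export
retrain_on_top_dims <- function(emb, balanced, labels, top, seed,
                                split_frac = 0.8, n_repeats = 3L,
                                full = NULL) {
  if (!length(top$dims)) stop_coex("top dimension set is empty")
  if (is.null(full)) {
    full <- train_models(emb, balanced, labels, split_frac = split_frac,
                         n_repeats = n_repeats, seed = seed,
                         model_kinds = top$model_kind)
  }
  restricted <- train_models(emb[, top$dims, drop = FALSE], balanced, labels,
                             split_frac = split_frac, n_repeats = n_repeats,
                             seed = seed, model_kinds = top$model_kind)
  acc_full <- accuracy_summary(full)
  acc_full <- acc_full$mean_accuracy[acc_full$model_kind == top$model_kind]
  acc_res <- accuracy_summary(restricted)$mean_accuracy[1L]
  list(model_kind = top$model_kind, full_accuracy = acc_full,
       restricted_accuracy = acc_res, ratio = acc_res / acc_full)
}
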