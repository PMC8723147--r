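# End-to-end pipeline: ingest -> (optional TOM build) -> modules -> embed ->
# embedding QC -> impact labeling + classifiers -> critical genes ->
# size-matched neighbor genes -> validation report. Every artifact carries
# the hash of the configuration that produced it.

#' Pipeline configuration
#'
#' Inputs may be file paths (read with the `netio` readers) or in-memory
#' objects. Every stochastic stage requires an explicit seed; validation
#' fails before any compute otherwise.
#'
#' @param dea DEA table or path (required).
#' @param expression Expression matrix or path (required unless `tom` given;
#'   also needed for trait correlations).
#' @param tom TOM matrix or path; built from `expression` with [build_tom()]
#'   when absent.
#' @param traits Trait table or path (optional).
#' @param regulators Gene-id vector, [gene_set()] or one-id-per-line file of
#'   candidate regulators for overlap validation (optional).
#' @param out_dir Output directory.
#' @param beta Soft-power exponent for TOM construction.
#' @param resolution Louvain resolution.
#' @param d,max_epoch,learning_rate,negative_ratio,total_samples Embedding
#'   knobs (see [embed_network()]).
#' @param percentile Impact-gene percentile (default 8).
#' @param n_repeats,split_frac Classifier protocol.
#' @param importance_cutoff Cumulative importance for top dimensions.
#' @param sigma,sigma_percentile Distance cutoff rule for critical genes.
#' @param alpha Significance cutoff for ANOVA / DEG calls.
#' @param top_n Genes per list in correlation validation.
#' @param seed Single integer from which all stage seeds derive, or a named
#'   list with `louvain`, `embed`, `balance`, `ml` entries.
#' @return list of class `run_config`.
#' @export
run_config <- function(dea, expression = NULL, tom = NULL, traits = NULL,
                       regulators = NULL, out_dir = "coexrank_run",
                       beta = 6, resolution = 1, d = 64L, max_epoch = 100L,
                       learning_rate = 0.1, negative_ratio = 0.15,
                       total_samples = 75, percentile = 8, n_repeats = 3L,
                       split_frac = 0.8, importance_cutoff = 0.5,
                       sigma = NULL, sigma_percentile = 5, alpha = 0.05,
                       top_n = 50L, seed) {
  if (missing(seed) || is.null(seed)) {
    stop_coex("run_config requires a seed (single integer or named list)")
  }
  if (is.numeric(seed) && length(seed) == 1L) {
    seed <- list(louvain = seed + 1L, embed = seed + 2L,
                 balance = seed + 3L, ml = seed + 4L)
  }
  need <- setdiff(c("louvain", "embed", "balance", "ml"), names(seed))
  if (length(need)) {
    stop_coex("missing seeds for stage(s): %s", paste(need, collapse = ", "))
  }
  if (is.null(expression) && is.null(tom)) {
    stop_coex("provide expression data, a TOM, or both")
  }
  cfg <- list(dea = dea, expression = expression, tom = tom, traits = traits,
              regulators = regulators, out_dir = out_dir, beta = beta,
              resolution = resolution, d = as.integer(d),
              max_epoch = as.integer(max_epoch),
              learning_rate = learning_rate,
              negative_ratio = negative_ratio,
              total_samples = total_samples, percentile = percentile,
              n_repeats = as.integer(n_repeats), split_frac = split_frac,
              importance_cutoff = importance_cutoff, sigma = sigma,
              sigma_percentile = sigma_percentile, alpha = alpha,
              top_n = as.integer(top_n), seed = seed)
  structure(cfg, class = "run_config")
}

load_input <- function(obj, reader) {
  if (is.null(obj)) NULL
  else if (is.character(obj) && length(obj) == 1L && file.exists(obj)) reader(obj)
  else obj
}

read_gene_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids) & !startsWith(ids, "#")]
}

#' Run the full critical-gene pipeline
#'
#' Executes every stage of the workflow and writes the artifacts (TOM is not
#' re-written when supplied), each stamped with the configuration hash:
#' `modules.tsv`, `embedding.tsv`, `qc_report.tsv`, `model_accuracy.tsv`,
#' `top_dimensions.tsv`, `critical.tsv`, `neighbors.tsv`,
#' `validation.tsv`, `config.yaml` and `run.log`. A QC failure (the
#' embedding preserving no module structure) warns and is flagged in the
#' report but does not abort.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  stamp <- sprintf("config: %s", hash)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      stop_coex("stage '%s' failed: %s", name, conditionMessage(e))
    })
    say("stage %s: done", name)
    out
  }

  dea <- stage("ingest", {
    dea <- load_input(cfg$dea, read_dea)
    expr <- load_input(cfg$expression, read_expression)
    tom <- load_input(cfg$tom, function(p) read_tom(p, "dense"))
    traits <- load_input(cfg$traits, read_traits)
    regulators <- if (is.character(cfg$regulators) &&
                      length(cfg$regulators) == 1L &&
                      file.exists(cfg$regulators)) {
      read_gene_list(cfg$regulators)
    } else cfg$regulators
    objs <- list(dea = dea)
    if (!is.null(expr)) objs$expression <- expr
    if (!is.null(tom)) objs$tom <- tom
    if (length(objs) > 1L) {
      al <- align_universe(objs)
      for (src in names(al$dropped)) {
        if (length(al$dropped[[src]])) {
          say("aligned universe drops %d ids from %s",
              length(al$dropped[[src]]), src)
        }
      }
      objs <- al$objects
    }
    list(dea = objs$dea, expression = objs$expression, tom = objs$tom,
         traits = traits, regulators = regulators)
  })
  inputs <- dea
  dea <- inputs$dea

  tom <- inputs$tom %||% stage("tom", build_tom(inputs$expression, cfg$beta))
  modules <- stage("modules",
                   louvain_modules(tom, cfg$resolution, seed = cfg$seed$louvain))
  say("louvain found %d modules", modules$n_groups)
  emb <- stage("embed",
               embed_network(tom, d = cfg$d, max_epoch = cfg$max_epoch,
                             learning_rate = cfg$learning_rate,
                             negative_ratio = cfg$negative_ratio,
                             total_samples = cfg$total_samples,
                             seed = cfg$seed$embed))
  clusters <- stage("cluster",
                    kmeans_clusters(emb, k = modules$n_groups,
                                    seed = cfg$seed$embed))

  degs <- gene_set("deg", deg_genes(dea, cfg$alpha))
  labels <- stage("label", label_impact(dea, cfg$percentile))
  qc <- NULL
  if (!is.null(inputs$expression) && !is.null(inputs$traits)) {
    # the concentration check needs a marker set; fall back to impact genes
    # when nothing clears the adjusted-p cutoff
    marker <- if (length(degs$gene_ids)) degs else
      gene_set("impact", labels$impact_genes)
    qc <- stage("qc", embedding_qc(inputs$expression, modules, clusters,
                                   marker, inputs$traits, alpha = cfg$alpha))
    qc_fail <- any(qc$trait_tests$p < 0.05, na.rm = TRUE)
    if (qc_fail) {
      warning("embedding QC flagged: module/cluster statistics differ")
    }
    say("qc: %s share in top-3 clusters = %.2f", marker$name,
        qc$deg_top3_share)
  } else {
    say("qc skipped (needs expression and traits)")
  }
  balanced <- stage("balance", balance_downsample(labels, seed = cfg$seed$balance))
  results <- stage("train",
                   train_models(emb, balanced, labels,
                                split_frac = cfg$split_frac,
                                n_repeats = cfg$n_repeats,
                                seed = cfg$seed$ml))
  acc <- accuracy_summary(results)
  tops <- lapply(setNames(MODEL_KINDS, MODEL_KINDS), function(k)
    select_top_dims(results, k, cutoff = cfg$importance_cutoff))
  retrain <- lapply(tops, function(top)
    retrain_on_top_dims(emb, balanced, labels, top, seed = cfg$seed$ml,
                        split_frac = cfg$split_frac,
                        n_repeats = cfg$n_repeats,
                        full = results))

  params <- proximity_params(sigma = cfg$sigma,
                             sigma_percentile = cfg$sigma_percentile)
  critical <- stage("critical",
                    critical_genes(emb, labels$impact_genes, tops, params))
  neighbors <- stage("neighbors",
                     match_list_sizes(tom, labels$impact_genes, critical))
  say("critical genes (count >= 1): %d; neighbor epsilon = %.4g",
      length(ranked_genes(critical)), neighbors$epsilon)

  validation <- stage("validate", {
    rows <- list()
    universe <- rownames(tom)
    cg <- ranked_genes(critical)
    ng <- ranked_genes(neighbors$ranking)
    add <- function(metric, value) {
      rows[[length(rows) + 1L]] <<- data.frame(metric = metric, value = value)
    }
    add("n_critical", length(cg))
    add("n_neighbor", length(ng))
    add("n_critical_non_deg", length(setdiff(cg, degs$gene_ids)))
    if (length(cg)) {
      add("pct_critical_non_deg",
          100 * length(setdiff(cg, degs$gene_ids)) / length(cg))
    }
    if (!is.null(inputs$regulators)) {
      ov_c <- overlap_test(cg, intersect(inputs$regulators, universe), universe)
      ov_n <- overlap_test(ng, intersect(inputs$regulators, universe), universe)
      add("critical_regulator_overlap", ov_c$k)
      add("critical_regulator_p", ov_c$p)
      add("neighbor_regulator_overlap", ov_n$k)
      add("neighbor_regulator_p", ov_n$p)
    }
    if (!is.null(inputs$expression) && !is.null(inputs$traits)) {
      lists <- list(critical = head(cg, cfg$top_n),
                    neighbor = head(ng, cfg$top_n),
                    deg = head(dea$gene_id[order(-abs(dea$log2fc))], cfg$top_n))
      lists <- Filter(function(l) length(l) >= 3L, lists)
      if (length(lists) >= 2L) {
        cors <- lapply(lists, gene_trait_cor, x = inputs$expression,
                       traits = inputs$traits)
        cmp <- compare_gene_lists_cor(cors)
        for (i in seq_len(nrow(cmp))) {
          add(sprintf("cor_cmp_%s_%s_%s", cmp$trait_name[i], cmp$test[i],
                      gsub(" ", "", cmp$comparison[i])), cmp$p[i])
        }
      }
    }
    do.call(rbind, rows)
  })

  stage("write", {
    write_tsv_file(data.frame(gene_id = names(modules$labels),
                              module = modules$labels),
                   file.path(cfg$out_dir, "modules.tsv"), stamp)
    write_embedding(emb, file.path(cfg$out_dir, "embedding.tsv"), stamp)
    write_tsv_file(acc, file.path(cfg$out_dir, "model_accuracy.tsv"), stamp)
    top_df <- do.call(rbind, lapply(tops, function(t)
      data.frame(model_kind = t$model_kind, dim = t$dim_names,
                 order = seq_along(t$dims),
                 cumulative_importance = t$cumulative_importance,
                 retrain_ratio = retrain[[t$model_kind]]$ratio)))
    write_tsv_file(top_df, file.path(cfg$out_dir, "top_dimensions.tsv"), stamp)
    write_ranking(critical, file.path(cfg$out_dir, "critical.tsv"), stamp)
    write_ranking(neighbors$ranking,
                  file.path(cfg$out_dir, "neighbors.tsv"),
                  c(stamp, sprintf("epsilon: %.10g", neighbors$epsilon)))
    if (!is.null(qc)) {
      qc_df <- rbind(data.frame(trait = "(deg)", statistic = "deg_top3_share",
                                t = NA_real_, p = NA_real_),
                     qc$trait_tests)
      qc_df$value <- c(qc$deg_top3_share, rep(NA_real_, nrow(qc$trait_tests)))
      write_tsv_file(qc_df, file.path(cfg$out_dir, "qc_report.tsv"), stamp)
    }
    if (!is.null(validation)) {
      write_tsv_file(validation, file.path(cfg$out_dir, "validation.tsv"),
                     stamp)
    }
    snap <- cfg
    for (f in c("dea", "expression", "tom", "traits", "regulators")) {
      if (!is.null(snap[[f]]) && !is.character(snap[[f]])) {
        snap[[f]] <- "<in-memory object>"
      }
    }
    snap$config_hash <- hash
    yaml::write_yaml(unclass(snap), file.path(cfg$out_dir, "config.yaml"))
    writeLines(c(paste0("# ", stamp), log_lines),
               file.path(cfg$out_dir, "run.log"))
    NULL
  })

  invisible(list(out_dir = cfg$out_dir, config_hash = hash, tom = tom,
                 modules = modules, embedding = emb, clusters = clusters,
                 qc = qc, labels = labels, balanced = balanced,
                 model_results = results, accuracy = acc, top_dims = tops,
                 retrain = retrain, critical = critical,
                 neighbors = neighbors, validation = validation))
}
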