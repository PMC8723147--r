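# Synthetic expression / DEA / trait generator with planted co-expression
# modules, small-effect DEGs and planted non-DE "regulator" genes.
#
# The model is a latent-factor one: each module has a per-sample standard
# normal factor; a member gene is loading * factor + Gaussian noise, so the
# within-module pairwise correlation equals loading^2. Planted regulators sit
# in a DEG-carrying module with a loading chosen so that their correlation
# with ordinary members of that module hits a target, but they receive no
# case/control mean shift. Traits are affine functions of one module's
# factor plus noise. Scaling is O(n_genes): no explicit covariance draw.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate a brain-tissue case/control study with small effect
#' sizes: 2000 genes in 8 co-expression modules, 60 cases + 60 controls,
#' within-module correlation 0.7, 160 DEGs (8 percent of genes) with
#' |log2 fold change| 0.3 planted in the first two modules, 40 regulator
#' genes co-expressed with the DEG modules at r = 0.7 but not themselves
#' shifted, and three traits tracking the factors of modules 1-3.
#'
#' @param n_genes,n_samples_per_group,n_modules Problem size.
#' @param within_module_cor Pairwise correlation between genes of one module.
#' @param n_deg Number of genes given a case-vs-control mean shift.
#' @param effect_size_log2fc Mean shift, on the log2 expression scale.
#' @param deg_modules Modules (1-based) that carry the DEGs and regulators.
#' @param n_planted_regulators Number of non-shifted, DEG-correlated genes.
#' @param regulator_to_deg_cor Target regulator-to-DEG-gene correlation;
#'   must not exceed `sqrt(within_module_cor)`.
#' @param trait_module_map Named integer vector mapping trait name to the
#'   module whose factor generates it.
#' @param trait_cor Target correlation between each trait and its factor.
#' @param gene_sd Per-gene expression standard deviation on the log2 scale
#'   (default 0.5, typical subject-to-subject variability of log2
#'   expression in bulk brain tissue). Correlations are unaffected; the
#'   ratio `effect_size_log2fc / gene_sd` sets how cleanly shifted genes
#'   stand out of the fold-change noise.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000L, n_samples_per_group = 60L,
                         n_modules = 8L, within_module_cor = 0.7,
                         n_deg = 160L, effect_size_log2fc = 0.3,
                         deg_modules = c(1L, 2L),
                         n_planted_regulators = 40L,
                         regulator_to_deg_cor = 0.7,
                         trait_module_map = c(audit = 1L,
                                              drinks_per_day = 2L,
                                              drinking_years = 3L),
                         trait_cor = 0.6, gene_sd = 0.5, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_modules = as.integer(n_modules),
              within_module_cor = within_module_cor,
              n_deg = as.integer(n_deg),
              effect_size_log2fc = effect_size_log2fc,
              deg_modules = as.integer(deg_modules),
              n_planted_regulators = as.integer(n_planted_regulators),
              regulator_to_deg_cor = regulator_to_deg_cor,
              trait_module_map = trait_module_map,
              trait_cor = trait_cor,
              gene_sd = gene_sd,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (n_modules < 1L || n_genes < n_modules) {
      stop_coex("need at least one gene per module")
    }
    if (within_module_cor <= 0 || within_module_cor >= 1) {
      stop_coex("within_module_cor must be in (0,1)")
    }
    if (abs(regulator_to_deg_cor) >= 1) {
      stop_coex("regulator_to_deg_cor must be in (-1,1)")
    }
    if (abs(trait_cor) >= 1) stop_coex("trait_cor must be in (-1,1)")
    if (gene_sd <= 0) stop_coex("gene_sd must be positive")
    if (n_deg + n_planted_regulators > n_genes) {
      stop_coex("n_deg + n_planted_regulators exceeds n_genes")
    }
    if (any(deg_modules < 1L | deg_modules > n_modules)) {
      stop_coex("deg_modules out of range")
    }
    if (any(!trait_module_map %in% seq_len(n_modules))) {
      stop_coex("trait_module_map references unknown module")
    }
    if (abs(regulator_to_deg_cor) > sqrt(within_module_cor)) {
      stop_coex(paste0("regulator_to_deg_cor cannot exceed ",
                       "sqrt(within_module_cor) = %.3f"),
                sqrt(within_module_cor))
    }
    n_deg_pool <- sum(tabulate(rep_len(seq_len(n_modules), n_genes),
                               n_modules)[deg_modules])
    if (n_deg + n_planted_regulators > n_deg_pool) {
      stop_coex("DEG modules hold %d genes; cannot plant %d DEGs + %d regulators",
                n_deg_pool, n_deg, n_planted_regulators)
    }
  })
  invisible(cfg)
}

# trait scale parameters (affine transforms; Pearson r is unaffected)
TRAIT_SCALES <- list(audit = c(mu = 60, sd = 30),
                     drinks_per_day = c(mu = 150, sd = 90),
                     drinking_years = c(mu = 30, sd = 10))

#' Generate a synthetic cohort
#'
#' @param cfg A [synth_config()].
#' @return list with `expression` (genes x samples matrix), `dea`
#'   (per-gene Welch t test with Benjamini-Hochberg adjustment), `traits`
#'   (long trait table), `truth` (planted ground truth: `module_of`,
#'   `factors` (samples x modules latent factors), `deg_set`,
#'   `regulator_set`, `trait_modules`, `loading`, `group`).
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  m <- cfg$n_modules
  ns <- 2L * cfg$n_samples_per_group
  gene_ids <- sprintf("g%05d", seq_len(n))
  sample_ids <- c(sprintf("case_%03d", seq_len(cfg$n_samples_per_group)),
                  sprintf("ctrl_%03d", seq_len(cfg$n_samples_per_group)))
  group <- rep(c("case", "ctrl"), each = cfg$n_samples_per_group)

  module_of <- rep_len(seq_len(m), n)
  names(module_of) <- gene_ids

  # plant regulators then DEGs inside the designated modules
  pool <- which(module_of %in% cfg$deg_modules)
  picked <- sample(pool, cfg$n_deg + cfg$n_planted_regulators)
  reg_idx <- picked[seq_len(cfg$n_planted_regulators)]
  deg_idx <- picked[cfg$n_planted_regulators + seq_len(cfg$n_deg)]

  loading <- rep(sqrt(cfg$within_module_cor), n)
  loading[reg_idx] <- cfg$regulator_to_deg_cor / sqrt(cfg$within_module_cor)
  names(loading) <- gene_ids

  factors <- matrix(rnorm(ns * m), ns, m)       # samples x modules
  noise_sd <- sqrt(1 - loading^2)
  x <- cfg$gene_sd * (t(factors[, module_of, drop = FALSE]) * loading +
                        matrix(rnorm(n * ns), n, ns) * noise_sd)
  x[deg_idx, group == "case"] <- x[deg_idx, group == "case"] +
    cfg$effect_size_log2fc
  dimnames(x) <- list(gene_ids, sample_ids)

  dea <- welch_dea(x, group == "case")

  traits <- do.call(rbind, lapply(names(cfg$trait_module_map), function(tn) {
    f <- factors[, cfg$trait_module_map[[tn]]]
    z <- cfg$trait_cor * f + sqrt(1 - cfg$trait_cor^2) * rnorm(ns)
    sc <- TRAIT_SCALES[[tn]] %||% c(mu = 0, sd = 1)
    trait_table(sample_ids, tn, sc[["mu"]] + sc[["sd"]] * z)
  }))

  dimnames(factors) <- list(sample_ids, paste0("module", seq_len(m)))
  truth <- structure(list(
    module_of = module_of,
    factors = factors,
    deg_set = gene_set("planted_deg", gene_ids[deg_idx]),
    regulator_set = gene_set("planted_regulator", gene_ids[reg_idx]),
    trait_modules = cfg$trait_module_map,
    loading = loading,
    group = setNames(group, sample_ids),
    config = cfg), class = "synth_truth")

  list(expression = expression_matrix(x), dea = dea,
       traits = traits, truth = truth)
}

#' Generate an independent replication cohort
#'
#' Fresh samples from the same latent-factor model (same module membership
#' and loadings) with no case/control shift, emulating a second post-mortem
#' cohort that shares co-expression structure but not subjects.
#'
#' @param cfg The [synth_config()] used for the first cohort.
#' @param truth The `truth` component returned by [synth_generate()].
#' @param n_samples Number of replication samples (default: same as cohort 1).
#' @param seed Seed for the new draws; defaults to `cfg$seed + 1`.
#' @return An [expression_matrix()] with new sample ids (`rep_*`).
#' @export
synth_second_cohort <- function(cfg, truth, n_samples = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  set.seed(seed %||% (cfg$seed + 1L))
  ns <- n_samples %||% (2L * cfg$n_samples_per_group)
  n <- length(truth$module_of)
  factors <- matrix(rnorm(ns * cfg$n_modules), ns, cfg$n_modules)
  noise_sd <- sqrt(1 - truth$loading^2)
  x <- cfg$gene_sd * (t(factors[, truth$module_of, drop = FALSE]) * truth$loading +
                        matrix(rnorm(n * ns), n, ns) * noise_sd)
  dimnames(x) <- list(names(truth$module_of), sprintf("rep_%03d", seq_len(ns)))
  expression_matrix(x)
}

#' Per-gene Welch two-sample t test with BH adjustment
#'
#' Vectorized over genes; the log2 fold change is the case-minus-control
#' mean difference of (log-scale) expression.
#'
#' @param x Expression matrix, genes x samples.
#' @param is_case Logical vector over samples.
#' @return A [dea_table()] with BH-adjusted p-values.
#' @export
welch_dea <- function(x, is_case) {
  stopifnot(is.matrix(x), length(is_case) == ncol(x))
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 < 2L || n2 < 2L) stop_coex("need >= 2 samples per group")
  x1 <- x[, is_case, drop = FALSE]; x2 <- x[, !is_case, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[!is.finite(tstat)] <- 1          # zero-variance genes: no evidence
  dea_table(rownames(x), m1 - m2, p.adjust(p, method = "BH"))
}
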