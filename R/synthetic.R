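# Seeded generators producing every input type the pipeline consumes, with
# the planted ground truth returned alongside so downstream recovery can be
# scored without touching real data.

#' Configuration for the pooled-count simulator
#'
#' Describes a pooled small-RNA-seq experiment: a handful of condition
#' groups, each sequenced as a small number of replicate pools, with
#' negative-binomial counts around a fixed per-miRNA baseline abundance.
#' Defaults emulate a three-group (healthy / tumor / metastatic) design with
#' duplicate pools per group and one planted miRNA whose abundance falls to
#' 0.64x in tumors and 0.55x in metastatic disease (log2 FCs of about
#' -0.64 and -0.86 against the healthy pools); all other miRNAs, including
#' the designated constant reference, are unchanged across groups.
#'
#' @param n_mirnas number of miRNAs simulated.
#' @param groups ordered character vector of group labels.
#' @param replicates_per_group pools per group (>= 2).
#' @param library_size expected total counts per pool.
#' @param dispersion negative-binomial dispersion; `0` gives the Poisson
#'   limit.
#' @param planted list of `list(mirna = <index>, effects = <per-group
#'   multipliers>)`; effects must be strictly positive and one per group.
#' @param seed integer seed; all randomness in [simulate_pool_counts()]
#'   derives from it.
#' @return a `pool_sim_config` list.
#' @export
pool_sim_config <- function(n_mirnas = 200,
                            groups = c("healthy", "tumor", "metastatic"),
                            replicates_per_group = 2,
                            library_size = 5e6,
                            dispersion = 0.05,
                            planted = list(list(mirna = 1L,
                                                effects = c(1, 0.64, 0.55))),
                            seed = 1L) {
  n_mirnas <- check_count(n_mirnas, "n_mirnas")
  if (!is.character(groups) || length(groups) < 2L || anyDuplicated(groups))
    mt_config_error("groups", "must be >= 2 distinct labels")
  replicates_per_group <- check_count(replicates_per_group, "replicates_per_group", 2L)
  check_number(library_size, "library_size", 0, strict_lower = TRUE)
  check_number(dispersion, "dispersion", 0)
  if (!is.list(planted)) mt_config_error("planted", "must be a list")
  for (p in planted) {
    if (is.null(p$mirna) || is.null(p$effects))
      mt_config_error("planted", "each entry needs 'mirna' and 'effects'")
    if (p$mirna < 1L || p$mirna > n_mirnas)
      mt_config_error("planted", "mirna index %s outside 1..n_mirnas", p$mirna)
    if (length(p$effects) != length(groups) || any(p$effects <= 0))
      mt_config_error("planted",
                      "effects must be strictly positive, one per group")
  }
  structure(list(n_mirnas = n_mirnas, groups = groups,
                 replicates_per_group = replicates_per_group,
                 library_size = library_size, dispersion = dispersion,
                 planted = planted, seed = check_count(seed, "seed", 0L)),
            class = "pool_sim_config")
}

#' Simulate a pooled miRNA count table with planted group effects
#'
#' Baseline relative abundances are drawn once (log-normal) and planted
#' miRNAs are multiplied by their per-group effect, so the expected count of
#' a planted miRNA in group *g* is `library_size * baseline_share *
#' effect(g)`. Counts are negative binomial with the configured dispersion
#' (Poisson at dispersion 0).
#'
#' @param config a [pool_sim_config()].
#' @return list with `table` (a [pool_count_table()]) and `truth`, a
#'   data.frame of the planted per-group effects.
#' @export
simulate_pool_counts <- function(config) {
  if (!inherits(config, "pool_sim_config"))
    mt_config_error("config", "must be a pool_sim_config")
  set.seed(child_seed(config$seed, 1))
  n <- config$n_mirnas
  k <- length(config$groups)
  r <- config$replicates_per_group
  mirna_ids <- sprintf("miRNA_%04d", seq_len(n))
  share <- exp(stats::rnorm(n, 0, 1.5))
  share <- share / sum(share)
  effects <- matrix(1, n, k)
  for (p in config$planted) effects[p$mirna, ] <- p$effects
  mu <- config$library_size * share * effects          # n x k expected counts
  mu_samp <- mu[, rep(seq_len(k), each = r), drop = FALSE]
  counts <-
    if (config$dispersion > 0) {
      matrix(stats::rnbinom(n * k * r, mu = mu_samp, size = 1 / config$dispersion),
             n, k * r)
    } else {
      matrix(stats::rpois(n * k * r, lambda = mu_samp), n, k * r)
    }
  sample_ids <- paste(rep(config$groups, each = r), rep(seq_len(r), k), sep = "_")
  dimnames(counts) <- list(mirna_ids, sample_ids)
  groups <- stats::setNames(rep(config$groups, each = r), sample_ids)
  truth <- do.call(rbind, lapply(config$planted, function(p) {
    data.frame(mirna_id = mirna_ids[p$mirna], group = config$groups,
               effect = p$effects, row.names = NULL)
  }))
  list(table = pool_count_table(counts, groups), truth = truth)
}

#' Configuration for the two-context expression simulator
#'
#' Emulates a microarray study of one cell line in two contexts (monolayer
#' and CSC-enriched cultures) under an ordered miRNA-activity gradient
#' (inhibitor < control < mimic), replicated per cell. Planted "promoted"
#' genes rise by `effect` log2 units per treatment step, planted "inhibited"
#' genes fall; when `consistent = FALSE` the direction is reversed in the
#' second context. All remaining genes are null (flat means). Gaussian noise
#' on the log2 scale.
#'
#' @param n_genes number of genes.
#' @param contexts ordered pair of context labels.
#' @param treatments ordered triple of treatment labels encoding increasing
#'   miRNA activity.
#' @param replicates replicates per (context, treatment) cell (>= 3,
#'   matching a triplicated array design).
#' @param noise_sd residual sd in log2 units.
#' @param planted_promoted,planted_inhibited lists of `list(gene = <index>,
#'   effect = <log2 per step>, consistent = <flag>)`; the two lists must be
#'   disjoint and effects strictly positive.
#' @param seed integer seed.
#' @return a `trend_sim_config` list.
#' @export
trend_sim_config <- function(n_genes = 1000,
                             contexts = c("monolayer", "CSC"),
                             treatments = c("inhibitor", "control", "mimic"),
                             replicates = 3,
                             noise_sd = 0.5,
                             planted_promoted = list(),
                             planted_inhibited = list(),
                             seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  if (length(contexts) != 2L || anyDuplicated(contexts))
    mt_config_error("contexts", "must be an ordered pair of distinct labels")
  if (length(treatments) != 3L || anyDuplicated(treatments))
    mt_config_error("treatments", "must be an ordered triple of distinct labels")
  replicates <- check_count(replicates, "replicates", 3L)
  check_number(noise_sd, "noise_sd", 0)
  chk <- function(lst, field) {
    for (p in lst) {
      if (is.null(p$gene) || is.null(p$effect))
        mt_config_error(field, "each entry needs 'gene' and 'effect'")
      if (p$gene < 1L || p$gene > n_genes)
        mt_config_error(field, "gene index %s outside 1..n_genes", p$gene)
      if (p$effect <= 0) mt_config_error(field, "effect sizes must be > 0")
    }
    vapply(lst, function(p) as.integer(p$gene), integer(1))
  }
  gp <- chk(planted_promoted, "planted_promoted")
  gi <- chk(planted_inhibited, "planted_inhibited")
  if (length(intersect(gp, gi)))
    mt_config_error("planted_inhibited", "planted lists must be disjoint")
  structure(list(n_genes = n_genes, contexts = contexts,
                 treatments = treatments, replicates = replicates,
                 noise_sd = noise_sd, planted_promoted = planted_promoted,
                 planted_inhibited = planted_inhibited,
                 seed = check_count(seed, "seed", 0L)),
            class = "trend_sim_config")
}

#' Simulate a two-context expression study with planted monotone trends
#'
#' @param config a [trend_sim_config()].
#' @return list with `study` (an [expression_study()]) and `truth`, a
#'   data.frame with one row per gene: `gene_id`, `class` (promoted /
#'   inhibited / null), `effect`, `consistent`.
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "trend_sim_config"))
    mt_config_error("config", "must be a trend_sim_config")
  set.seed(child_seed(config$seed, 2))
  n <- config$n_genes
  r <- config$replicates
  gene_ids <- sprintf("gene_%05d", seq_len(n))
  design <- expand.grid(replicate = seq_len(r),
                        treatment = config$treatments,
                        context = config$contexts,
                        stringsAsFactors = FALSE)[, c("context", "treatment", "replicate")]
  design$sample <- paste(design$context, design$treatment, design$replicate, sep = "_")
  baseline <- stats::runif(n, 4, 12)
  step <- match(design$treatment, config$treatments) - 1L   # 0,1,2
  second_ctx <- design$context == config$contexts[2L]
  mu <- matrix(baseline, n, nrow(design))
  slope <- numeric(n)            # signed per-step effect, first context
  flip <- logical(n)             # reversed in second context?
  class <- rep("null", n)
  for (p in config$planted_promoted) {
    slope[p$gene] <- p$effect
    flip[p$gene] <- isFALSE(p$consistent)
    class[p$gene] <- "promoted"
  }
  for (p in config$planted_inhibited) {
    slope[p$gene] <- -p$effect
    flip[p$gene] <- isFALSE(p$consistent)
    class[p$gene] <- "inhibited"
  }
  sgn <- outer(flip, second_ctx, function(f, s) ifelse(f & s, -1, 1))
  mu <- mu + (slope * sgn) * matrix(step, n, nrow(design), byrow = TRUE)
  expr <- mu + matrix(stats::rnorm(n * nrow(design), 0, config$noise_sd),
                      n, nrow(design))
  dimnames(expr) <- list(gene_ids, design$sample)
  truth <- data.frame(gene_id = gene_ids, class = class,
                      effect = abs(slope),
                      consistent = class != "null" & !flip)
  list(study = expression_study(expr, design[, c("sample", "context",
                                                 "treatment", "replicate")],
                                contexts = config$contexts,
                                treatments = config$treatments),
       truth = truth)
}

#' Simulate a long-format qPCR Ct table with a known fold change
#'
#' The reference assays have constant expected Ct across conditions; the
#' target assay is shifted by `target_shift` cycles in the treated
#' condition, so the true treated-vs-calibrator fold change is
#' `2^(-target_shift)`. With `noise_sd = 0` (the default) the table is
#' deterministic and the fold change is recovered exactly.
#'
#' @param n_samples samples per condition (>= 1).
#' @param target_shift Ct shift of the target in the treated condition.
#' @param seed integer seed.
#' @param noise_sd replicate-level Ct noise sd (cycles).
#' @param conditions pair of condition labels; the first is the calibrator.
#' @param replicates technical replicates per (sample, assay).
#' @param reference_assays names of the reference assays.
#' @return list with `table` (a [ct_table()]), `true_fc`, and
#'   `calibrator`.
#' @export
simulate_ct_table <- function(n_samples, target_shift, seed = 1L,
                              noise_sd = 0,
                              conditions = c("control", "treated"),
                              replicates = 3,
                              reference_assays = "REF1") {
  n_samples <- check_count(n_samples, "n_samples")
  check_number(target_shift, "target_shift")
  check_number(noise_sd, "noise_sd", 0)
  replicates <- check_count(replicates, "replicates")
  if (length(conditions) != 2L || anyDuplicated(conditions))
    mt_config_error("conditions", "must be two distinct labels")
  set.seed(child_seed(seed, 3))
  assays <- c("TARGET", reference_assays)
  base_ct <- stats::setNames(c(25, 20 + seq_along(reference_assays) - 1), assays)
  rows <- expand.grid(replicate = seq_len(replicates), assay = assays,
                      sample_idx = seq_len(n_samples), condition = conditions,
                      stringsAsFactors = FALSE)
  rows$sample <- paste(rows$condition, rows$sample_idx, sep = "_")
  rows$ct <- base_ct[rows$assay] +
    ifelse(rows$assay == "TARGET" & rows$condition == conditions[2L],
           target_shift, 0) +
    stats::rnorm(nrow(rows), 0, noise_sd)
  tab <- ct_table(rows[, c("sample", "condition", "assay", "replicate", "ct")])
  list(table = tab, true_fc = 2^(-target_shift), calibrator = conditions[1L])
}

#' Configuration for the meta-analysis study simulator
#'
#' @param n_studies number of studies (>= 1).
#' @param true_smd population standardized mean difference.
#' @param tau2 between-study variance of the true effects.
#' @param n_range integer interval for per-arm sample sizes (lower bound
#'   >= 2).
#' @param seed integer seed.
#' @return a `meta_sim_config` list.
#' @export
meta_sim_config <- function(n_studies = 5, true_smd = 1.01, tau2 = 0.05,
                            n_range = c(80, 120), seed = 1L) {
  n_studies <- check_count(n_studies, "n_studies")
  check_number(true_smd, "true_smd")
  check_number(tau2, "tau2", 0)
  if (length(n_range) != 2L || n_range[1] < 2L || n_range[2] < n_range[1])
    mt_config_error("n_range", "must be an integer interval with lower bound >= 2")
  structure(list(n_studies = n_studies, true_smd = true_smd, tau2 = tau2,
                 n_range = as.integer(round(n_range)),
                 seed = check_count(seed, "seed", 0L)),
            class = "meta_sim_config")
}

#' Simulate per-study case-control summaries around a known SMD
#'
#' Each study's true effect is drawn as `true_smd + N(0, tau2)`; observed
#' arm means are drawn from their exact normal sampling distributions
#' (unit within-arm sd) and arm sds from the scaled chi-square sampling
#' distribution, so the summaries are internally consistent with the
#' study's true effect.
#'
#' @param config a [meta_sim_config()].
#' @return list with `studies` (a study-summary data.frame, see
#'   [as_study_summaries()]) and `true_smd`.
#' @export
simulate_meta_studies <- function(config) {
  if (!inherits(config, "meta_sim_config"))
    mt_config_error("config", "must be a meta_sim_config")
  set.seed(child_seed(config$seed, 4))
  k <- config$n_studies
  theta <- config$true_smd + stats::rnorm(k, 0, sqrt(config$tau2))
  n_case <- sample(config$n_range[1]:config$n_range[2], k, replace = TRUE)
  n_control <- sample(config$n_range[1]:config$n_range[2], k, replace = TRUE)
  studies <- data.frame(
    study = sprintf("study_%02d", seq_len(k)),
    n_case = n_case,
    mean_case = stats::rnorm(k, theta, 1 / sqrt(n_case)),
    sd_case = sqrt(stats::rchisq(k, n_case - 1) / (n_case - 1)),
    n_control = n_control,
    mean_control = stats::rnorm(k, 0, 1 / sqrt(n_control)),
    sd_control = sqrt(stats::rchisq(k, n_control - 1) / (n_control - 1))
  )
  list(studies = as_study_summaries(studies), true_smd = config$true_smd)
}
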