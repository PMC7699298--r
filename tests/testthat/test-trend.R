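# Jonckheere-Terpstra machinery and the genome-wide screen: worked
# examples, independent oracles (Mann-Whitney pairwise counting and
# brute-force enumeration), tie conventions, stratified combined trend,
# and screen operating behaviour.

test_that("JT statistic: worked examples and tie convention", {
  g3 <- factor(rep(c("A", "B", "C"), each = 2), levels = c("A", "B", "C"))
  expect_equal(jt_statistic(1:6, g3), 12)                 # maximum 3 * 2 * 2
  expect_equal(jt_statistic(6:1, g3), 0)                  # perfect reversal
  expect_equal(jt_statistic(rep(1, 6), g3), 6)            # all ties: half of 12
  expect_error(jt_statistic(1:4, factor(rep("A", 4))), "2 ordered groups")
})

test_that("JT equals the Mann-Whitney pairwise-count oracle on random data", {
  set.seed(7)
  for (rep in 1:20) {
    sizes <- sample(2:4, sample(2:4, 1), replace = TRUE)
    gi <- rep(seq_along(sizes), sizes)
    x <- round(rnorm(length(gi)), 1)      # rounding induces ties
    expect_equal(jt_statistic(x, gi), oracle_jt(x, gi))
  }
})

test_that("JT complement identity: forward plus reversed equals all pairs", {
  set.seed(8)
  for (rep in 1:20) {
    sizes <- sample(2:4, 3, replace = TRUE)
    gi <- rep(1:3, sizes)
    x <- round(rnorm(length(gi)), 1)
    total <- sum(sizes[1] * sizes[2] + sizes[1] * sizes[3] +
                   sizes[2] * sizes[3])
    expect_equal(jt_statistic(x, gi) + jt_statistic(x, 4 - gi), total)
  }
})

test_that("exact permutation p: 1/90 worked example and oracle agreement", {
  g3 <- rep(1:3, each = 2)
  p <- jt_permutation_p(1:6, g3, "increasing", exact = TRUE)
  expect_equal(as.numeric(p), 1 / 90)
  expect_equal(attr(p, "n_assignments"), 90)
  set.seed(9)
  for (rep in 1:3) {
    x <- round(rnorm(6), 1)
    expect_equal(as.numeric(jt_permutation_p(x, g3, "increasing", exact = TRUE)),
                 oracle_exact_jt_p(x, g3, "increasing"))
    expect_equal(as.numeric(jt_permutation_p(x, g3, "decreasing", exact = TRUE)),
                 oracle_exact_jt_p(x, g3, "decreasing"))
  }
  g23 <- rep(1:2, c(2, 3))
  x <- c(0.3, 1.1, 0.2, 0.9, 1.4)
  expect_equal(as.numeric(jt_permutation_p(x, g23, "increasing", exact = TRUE)),
               oracle_exact_jt_p(x, g23, "increasing"))
})

test_that("Monte-Carlo p converges to the exact p and is seed-deterministic", {
  set.seed(10)
  x <- rnorm(8)
  gi <- rep(1:4, each = 2)
  pe <- as.numeric(jt_permutation_p(x, gi, "increasing", exact = TRUE))
  pm <- as.numeric(jt_permutation_p(x, gi, "increasing", n_perm = 10000,
                                    seed = 1))
  se <- sqrt(pe * (1 - pe) / 10000)
  expect_lt(abs(pm - pe), 3 * se + 1e-4)
  expect_identical(jt_permutation_p(x, gi, "increasing", n_perm = 500, seed = 3),
                   jt_permutation_p(x, gi, "increasing", n_perm = 500, seed = 3))
  expect_error(jt_permutation_p(x, gi, n_perm = 0), "n_perm")
  expect_warning(jt_permutation_p(x, gi, n_perm = 50, seed = 1), "coarse")
})

test_that("type-I error of the trend test is at most nominal under the null", {
  set.seed(12)
  gi <- rep(1:3, each = 3)
  rej <- mean(replicate(400, {
    as.numeric(jt_permutation_p(rnorm(9), gi, "increasing",
                                n_perm = 400)) <= 0.05
  }))
  expect_lte(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("direction classification follows the ordered gradient", {
  up <- toy_study(c(1, 2, 3), c(1, 2, 3), jitter = cell_jitter(2))
  expect_equal(classify_direction(up, "g1"), "promoted")
  down <- toy_study(c(3, 2, 1), c(3, 2, 1), jitter = cell_jitter(2))
  expect_equal(classify_direction(down, "g1"), "inhibited")
  flat <- toy_study(c(1, 1, 1), c(1, 1, 1))
  expect_equal(classify_direction(flat, "g1"), "degenerate")
})

test_that("combined transition trend: extreme ordering attains the minimal p", {
  # strictly increasing through all six groups, noiseless, distinct values
  st <- toy_study(c(1, 2, 3), c(4, 5, 6), jitter = cell_jitter(2))
  p <- combined_transition_trend(st, "g1", "promoted", exact = TRUE)
  expect_equal(attr(p, "n_assignments"), 90 * 90)
  expect_equal(as.numeric(p), 1 / (90 * 90))
})

test_that("combined trend nulls: stratified pools contexts, unstratified demands progression", {
  # trends within each context, but CSC levels sit below the monolayer top
  st <- toy_study(c(1, 2, 3), c(0, 1, 1.5), jitter = cell_jitter(2))
  mono <- st$design$context == "monolayer"
  trt <- match(st$design$treatment, c("inhibitor", "control", "mimic"))
  p_mono <- as.numeric(jt_permutation_p(st$expr[1, mono], trt[mono],
                                        "increasing", exact = TRUE))
  # stratified null blocks out the between-context level shift: the
  # cross-context pairs are permutation-invariant, so two perfect
  # within-context orderings give the minimal attainable p
  p_strat <- as.numeric(combined_transition_trend(st, "g1", "promoted",
                                                  exact = TRUE))
  expect_equal(p_strat, 1 / 8100)
  # unstratified null additionally requires progression across the
  # transition, which this gene lacks: its p falls behind the per-context p
  p_unstrat <- as.numeric(combined_transition_trend(
    st, "g1", "promoted", n_perm = 20000, seed = 1, null = "unstratified"))
  expect_gt(p_unstrat, p_mono)
  # a gene progressing through all six groups stays extreme under both
  prog <- toy_study(c(1, 2, 3), c(4, 5, 6), jitter = cell_jitter(2))
  p_prog <- as.numeric(combined_transition_trend(
    prog, "g1", "promoted", n_perm = 20000, seed = 1, null = "unstratified"))
  expect_lt(p_prog, 0.001)
})

test_that("stratified exact combined p matches the block-wise oracle", {
  # two contexts x two treatments x two replicates: 36 assignments
  design <- expand.grid(replicate = 1:2, treatment = c("inhibitor", "mimic"),
                        context = c("monolayer", "CSC"),
                        stringsAsFactors = FALSE)[, c("context", "treatment",
                                                      "replicate")]
  design$sample <- paste(design$context, design$treatment, design$replicate,
                         sep = "_")
  set.seed(13)
  x <- round(rnorm(8), 1)
  ctx <- match(design$context, c("monolayer", "CSC"))
  trt <- match(design$treatment, c("inhibitor", "mimic"))
  gi <- (ctx - 1L) * 2L + trt
  p_pkg <- mirtrend:::jt_exact_p(x, gi, "increasing", blocks = ctx)
  p_orc <- oracle_exact_jt_p(x, gi, "increasing", blocks = ctx)
  expect_equal(p_pkg$p, p_orc)
})

test_that("screen recovers planted genes and controls false flags", {
  noise <- 0.5
  planted <- lapply(1:50, function(i)
    list(gene = i, effect = 2 * noise, consistent = TRUE))
  sim <- simulate_expression(trend_sim_config(
    n_genes = 1000, noise_sd = noise, planted_promoted = planted, seed = 1))
  res <- trend_screen(sim$study, n_perm = 500, seed = 1, correction = "none")
  flagged <- res$gene_id[res$consistent_with_hypothesis]
  truth_pos <- sim$truth$gene_id[sim$truth$class == "promoted"]
  expect_gte(length(intersect(flagged, truth_pos)), 40)
  false_pos <- setdiff(flagged, truth_pos)
  # null flag needs both contexts significant and matching directions
  expect_lte(length(false_pos), 5)
  s <- attr(res, "summary")
  expect_equal(s$n_genes, 1000)
  expect_equal(s$n_consistent_with_hypothesis, length(flagged))
})

test_that("genes with opposite directions in the two contexts are never consistent", {
  st <- toy_study(c(1, 2, 3), c(3, 2, 1), reps = 3, jitter = cell_jitter(3))
  res <- trend_screen(st, n_perm = 500, seed = 2, correction = "none")
  expect_false(res$consistent_with_hypothesis[1])
  expect_equal(res$direction_monolayer[1], "promoted")
  expect_equal(res$direction_csc[1], "inhibited")
})

test_that("screen is invariant to gene order and respects curated lists", {
  sim <- simulate_expression(trend_sim_config(
    n_genes = 12, noise_sd = 0.4,
    planted_promoted = list(list(gene = 1, effect = 1.2, consistent = TRUE)),
    seed = 14))
  res <- trend_screen(sim$study, n_perm = 300, seed = 7, correction = "none")
  perm <- rev(seq_len(nrow(sim$study$expr)))
  shuffled <- expression_study(sim$study$expr[perm, ], sim$study$design,
                               sim$study$contexts, sim$study$treatments)
  res2 <- trend_screen(shuffled, n_perm = 300, seed = 7, correction = "none")
  m <- match(res$gene_id, res2$gene_id)
  expect_equal(res$p_trend_mono, res2$p_trend_mono[m])
  expect_equal(res$p_trend, res2$p_trend[m])
  # curated intersection bookkeeping
  res3 <- trend_screen(sim$study, gene_list = c("gene_00001", "nothere"),
                       n_perm = 300, seed = 7, correction = "none")
  s <- attr(res3, "summary")
  expect_equal(s$n_curated, 2)
  expect_true(res3$in_curated[res3$gene_id == "gene_00001"])
  disjoint <- trend_screen(sim$study, gene_list = c("absent_gene"),
                           n_perm = 300, seed = 7, correction = "none")
  expect_equal(attr(disjoint, "summary")$n_consistent_in_curated, 0)
})

test_that("BH and max-T corrections only make calls more conservative", {
  sim <- simulate_expression(trend_sim_config(
    n_genes = 40, noise_sd = 0.5,
    planted_promoted = lapply(1:5, function(i)
      list(gene = i, effect = 1.5, consistent = TRUE)),
    seed = 15))
  raw <- trend_screen(sim$study, n_perm = 300, seed = 4, correction = "none")
  bh <- trend_screen(sim$study, n_perm = 300, seed = 4, correction = "bh")
  expect_equal(raw$p_trend_mono, bh$p_trend_mono)   # same child streams
  expect_true(all(bh$adj_p_mono >= bh$p_trend_mono - 1e-12, na.rm = TRUE))
  expect_true(all(bh$consistent_with_hypothesis <= raw$consistent_with_hypothesis))
  mt <- trend_screen(sim$study, n_perm = 300, seed = 4, correction = "maxt")
  expect_true(all(mt$adj_p_mono >= mt$p_trend_mono - 1e-12, na.rm = TRUE))
  expect_true(all(mt$adj_p_csc >= mt$p_trend_csc - 1e-12, na.rm = TRUE))
})

test_that("four-arm designs collapse or tie the control arms equivalently", {
  treatments <- c("inhibitor", "inhibitor_control", "mimic_control", "mimic")
  design <- expand.grid(replicate = 1:2, treatment = treatments,
                        context = c("monolayer", "CSC"),
                        stringsAsFactors = FALSE)[, c("context", "treatment",
                                                      "replicate")]
  design$sample <- paste(design$context, design$treatment, design$replicate,
                         sep = "_")
  lvl <- match(design$treatment, treatments)
  set.seed(16)
  x <- c(1, 1.2, 2, 2.1, 2.2, 2.3, 3, 3.1)[lvl] + rnorm(16, 0, 0.01)
  st <- expression_study(matrix(x, 1, 16, dimnames = list("g1", design$sample)),
                         design, treatments = treatments)
  r3 <- trend_screen(st, n_perm = 400, seed = 5, correction = "none",
                     arms = "three")
  r4 <- trend_screen(st, n_perm = 400, seed = 5, correction = "none",
                     arms = "four")
  expect_equal(r3$jt_mono, r4$jt_mono)
  expect_equal(r3$p_trend_mono, r4$p_trend_mono)
})

test_that("screen ranking is signed and sorted", {
  sim <- simulate_expression(trend_sim_config(
    n_genes = 10, noise_sd = 0.3,
    planted_promoted = list(list(gene = 1, effect = 1.5, consistent = TRUE)),
    planted_inhibited = list(list(gene = 2, effect = 1.5, consistent = TRUE)),
    seed = 17))
  res <- trend_screen(sim$study, n_perm = 300, seed = 3, correction = "none")
  rk <- screen_ranking(res)
  expect_equal(nrow(rk), 10)
  expect_true(!is.unsorted(rev(rk$score)))
  expect_equal(rk$gene_id[1], "gene_00001")          # strongest promoted
  expect_equal(rk$gene_id[nrow(rk)], "gene_00002")   # strongest inhibited
})
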