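# TMM factors, fold changes on the shipped serum pool example, t/ANOVA
# conventions, BH adjustment, and the median-reads filter.

serum <- read_count_table(
  system.file("extdata", "serum_pool_mirseq.tsv", package = "mirtrend"),
  system.file("extdata", "serum_pool_design.tsv", package = "mirtrend"))

toy_table <- function(counts, groups) {
  dimnames(counts) <- list(sprintf("m%02d", seq_len(nrow(counts))),
                           sprintf("s%d", seq_len(ncol(counts))))
  pool_count_table(counts, groups)
}

test_that("TMM factors: symmetry, depth absorption, row-order invariance", {
  set.seed(1)
  base <- matrix(rnbinom(200, mu = 200, size = 5), 100, 2)
  tab <- toy_table(cbind(base[, 1], base[, 1]), c("a", "b"))
  expect_equal(unname(tmm_factors(tab)), c(1, 1), tolerance = 1e-12)
  tab2 <- toy_table(cbind(base[, 1], 2 * base[, 1]), c("a", "b"))
  expect_equal(unname(tmm_factors(tab2)), c(1, 1), tolerance = 1e-12)
  tab3 <- toy_table(cbind(base[, 1], base[, 2]), c("a", "b"))
  perm <- sample(nrow(base))
  tab3p <- pool_count_table(tab3$counts[perm, ], tab3$groups)
  expect_equal(unname(tmm_factors(tab3)), unname(tmm_factors(tab3p)))
})

test_that("scaling one sample's depth leaves its normalised values unchanged", {
  set.seed(2)
  counts <- matrix(rnbinom(300, mu = 150, size = 3), 100, 3)
  tab <- toy_table(counts, c("a", "a", "b"))
  norm1 <- tmm_normalize(tab)$normalized
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * 7
  tab2 <- toy_table(counts2, c("a", "a", "b"))
  norm2 <- tmm_normalize(tab2)$normalized
  # near-invariance: the trimmed-mean weights depend on raw counts, so a
  # pure depth change shifts the factor slightly (< 2 percent here)
  expect_equal(norm1[, 2], norm2[, 2], tolerance = 0.02)
  f <- tmm_factors(tab)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  expect_true(all(f > 0))
})

test_that("TMM errors identify degenerate inputs", {
  counts <- matrix(c(5, 5, 0, 0), 2, 2)
  expect_error(tmm_factors(toy_table(counts, c("a", "b"))), "s2")
  one <- matrix(1:3, 3, 1, dimnames = list(letters[1:3], "s1"))
  expect_error(tmm_factors(pool_count_table(one, c(s1 = "a"))), "2 samples")
})

test_that("serum pool example reproduces the printed group fold changes", {
  fc_mt <- log2_group_fc(serum, "hsa-miR-486-5p", "tumor", "metastatic")
  expect_equal(round(fc_mt, 2), -0.22)
  fc_mn <- log2_group_fc(serum, "hsa-miR-486-5p", "non_tumor", "metastatic")
  expect_equal(fc_mn, -0.8589, tolerance = 1e-3)
  fc_tn <- log2_group_fc(serum, "hsa-miR-486-5p", "non_tumor", "tumor")
  expect_equal(fc_tn, -0.6383, tolerance = 1e-3)
})

test_that("fold change identities and error cases", {
  counts <- matrix(c(10, 20, 10, 20, 5, 8, 5, 8), 2, 4)
  tab <- toy_table(counts, c("a", "b", "a", "b"))
  expect_equal(log2_group_fc(tab, "m01", "a", "a"), 0)
  expect_equal(log2_group_fc(tab, "m01", "a", "b"),
               -log2_group_fc(tab, "m01", "b", "a"))
  zc <- matrix(c(0, 3, 0, 4, 2, 5, 1, 6), 2, 4)
  ztab <- toy_table(zc, c("a", "a", "b", "b"))
  expect_error(log2_group_fc(ztab, "m01", "a", "b"), "undefined fold change")
})

test_that("per-miRNA t-test matches the closed form and base R", {
  counts <- rbind(c(1, 2, 3, 4), c(1, 2, 1, 2), c(5, 5, 5, 5))
  tab <- toy_table(counts, c("a", "a", "b", "b"))
  p <- per_mirna_ttest(tab, "a", "b")
  expect_equal(unname(p[1]), 2 * pt(-2.8284271, 2), tolerance = 1e-6)
  expect_equal(unname(p[1]),
               t.test(c(3, 4), c(1, 2), var.equal = TRUE)$p.value)
  expect_equal(unname(p[2]), 1)        # identical groups
  expect_equal(unname(p[3]), 1)        # flat feature, equal means
  # zero variance, different means -> epsilon convention p = 0
  d <- toy_table(rbind(c(1, 1, 2, 2)), c("a", "a", "b", "b"))
  expect_equal(unname(per_mirna_ttest(d, "a", "b")), 0)
  # Welch flag agrees with base R
  set.seed(3)
  r <- toy_table(rbind(rnorm(6) + 10), c("a", "a", "a", "b", "b", "b"))
  expect_equal(unname(per_mirna_ttest(r, "a", "b", var_equal = FALSE)),
               t.test(r$counts[1, 4:6], r$counts[1, 1:3])$p.value)
})

test_that("per-miRNA ANOVA matches the F closed form and base R", {
  counts <- rbind(c(1, 2, 3, 4, 5, 6), c(7, 7, 7, 7, 7, 7))
  tab <- toy_table(counts, rep(c("a", "b", "c"), each = 2))
  p <- per_mirna_anova(tab)
  # groups (1,2), (3,4), (5,6): MSB = 8, MSW = 0.5, so F = 16 on (2, 3) df
  expect_equal(unname(p[1]), pf(16, 2, 3, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(unname(p[1]),
               oneway.test(x ~ g, data.frame(x = counts[1, ],
                                             g = rep(letters[1:3], each = 2)),
                           var.equal = TRUE)$p.value)
  expect_equal(unname(p[2]), 1)
  deg <- toy_table(rbind(c(0, 0, 0, 0, 1, 1)), rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(per_mirna_anova(deg)), 0)
})

test_that("BH adjustment: worked example, identities, order invariance", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(4)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "p_values")
})

test_that("median-reads filter applies the strict per-group rule", {
  counts <- rbind(c(21, 21, 0, 0), c(20, 20, 20, 20), c(0, 0, 25, 30))
  tab <- toy_table(counts, c("a", "a", "b", "b"))
  kept <- filter_min_median_reads(tab, 20)
  expect_setequal(kept, c("m01", "m03"))
  # group medians at the stool example's printed levels pass in both groups
  stool <- toy_table(rbind(c(43.65, 43.65, 223.67, 223.67)),
                     c("control", "control", "crc", "crc"))
  expect_equal(filter_min_median_reads(stool, 20), "m01")
})

test_that("compare_groups assembles fold changes, p and FDR coherently", {
  cmp <- compare_groups(serum, "tumor", "metastatic", use_normalized = FALSE)
  expect_true(all(cmp$fdr_adjusted_p >= cmp$p_value - 1e-12))
  row <- cmp[cmp$mirna_id == "hsa-miR-486-5p", ]
  expect_equal(round(row$log2_fc, 2), -0.22)
  expect_true(is.na(cmp$log2_fc[cmp$mirna_id == "hsa-miR-431-5p"]))
})
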