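# Pooled small-RNA-seq group comparison: TMM scale factors, normalisation,
# group log2 fold changes, per-feature t / ANOVA tests with BH FDR, and the
# abundance filter used for stool libraries.

#' Construct a pooled miRNA count table
#'
#' @param counts non-negative numeric matrix, miRNAs in rows and samples in
#'   columns, with row and column names. Values are usually integer read
#'   counts; pre-averaged pool tables with decimal copy numbers are
#'   accepted.
#' @param groups group label per sample: either a named character vector
#'   (names = sample ids) or an unnamed vector in column order.
#' @return a `pool_count_table` (list with `counts` and `groups`).
#' @export
pool_count_table <- function(counts, groups) {
  if (!is.matrix(counts) || !is.numeric(counts))
    mt_config_error("counts", "must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    mt_config_error("counts", "must have miRNA row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    mt_config_error("counts", "duplicate miRNA ids")
  if (anyDuplicated(colnames(counts)))
    mt_config_error("counts", "duplicate sample ids")
  if (any(!is.finite(counts)) || any(counts < 0))
    mt_config_error("counts", "must be finite and non-negative")
  if (is.null(names(groups))) {
    if (length(groups) != ncol(counts))
      mt_config_error("groups", "length must match the number of samples")
    groups <- stats::setNames(as.character(groups), colnames(counts))
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing))
    mt_config_error("groups", "samples without a group: %s",
                    paste(missing, collapse = ", "))
  groups <- groups[colnames(counts)]
  structure(list(counts = counts, groups = groups), class = "pool_count_table")
}

#' @export
print.pool_count_table <- function(x, ...) {
  cat("pool_count_table:", nrow(x$counts), "miRNAs x", ncol(x$counts),
      "samples;", length(unique(x$groups)), "groups\n")
  invisible(x)
}

count_matrix <- function(table) {
  if (inherits(table, "pool_count_table")) return(table$counts)
  if (inherits(table, "normalized_table")) return(table$normalized)
  mt_config_error("table", "must be a pool_count_table or normalized_table")
}

table_groups <- function(table) {
  if (inherits(table, "normalized_table")) table$source$groups else table$groups
}

#' TMM scale factors for a pooled count table
#'
#' Trimmed-mean-of-M-values scale factors: per-sample factors estimated from
#' trimmed log-ratios (M) and log-abundances (A) against a reference sample,
#' rescaled so their geometric mean is 1. Computation is delegated to the
#' reference implementation of the method (edgeR's `calcNormFactors`), with
#' its canonical defaults: reference = sample whose upper-quartile count is
#' closest to the mean upper quartile, 30% trim on M, 5% trim on A,
#' inverse-variance weighting, and exclusion of features with a zero in
#' either sample.
#'
#' @param table a [pool_count_table()].
#' @param reference_sample optional sample id to use as reference.
#' @return named numeric vector of positive factors, one per sample.
#' @export
tmm_factors <- function(table, reference_sample = NULL) {
  counts <- count_matrix(table)
  if (ncol(counts) < 2L)
    mt_stop("TMM needs at least 2 samples")
  zero <- colSums(counts) <= 0
  if (any(zero))
    mt_stop("sample(s) with all-zero counts: %s",
            paste(colnames(counts)[zero], collapse = ", "))
  ref <- NULL
  if (!is.null(reference_sample)) {
    ref <- match(reference_sample, colnames(counts))
    if (is.na(ref))
      mt_config_error("reference_sample", "unknown sample '%s'", reference_sample)
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref)
  stats::setNames(as.numeric(f), colnames(counts))
}

#' TMM-normalised counts
#'
#' Divides each sample by its effective library size (raw library size times
#' TMM factor) and rescales to counts per million, so a pure depth change in
#' one sample leaves its normalised values untouched.
#'
#' @param table a [pool_count_table()].
#' @param reference_sample passed to [tmm_factors()].
#' @return a `normalized_table` (list with `source`, `scale_factors`,
#'   `normalized`).
#' @export
tmm_normalize <- function(table, reference_sample = NULL) {
  if (!inherits(table, "pool_count_table"))
    mt_config_error("table", "must be a pool_count_table")
  f <- tmm_factors(table, reference_sample)
  lib <- colSums(table$counts)
  normalized <- sweep(table$counts, 2, lib * f, "/") * 1e6
  structure(list(source = table, scale_factors = f, normalized = normalized),
            class = "normalized_table")
}

#' Log2 fold change between two group means
#'
#' `log2(mean(group_b) / mean(group_a))` for one miRNA, computed on raw
#' counts (`use_normalized = FALSE`, the scale of printed pool-average
#' tables) or on TMM-normalised values.
#'
#' @param table a [pool_count_table()] or [tmm_normalize()] result.
#' @param mirna_id feature to compare.
#' @param group_a,group_b group labels (baseline first).
#' @param use_normalized if `TRUE` and `table` is raw, TMM-normalise first.
#' @return a single log2 fold change.
#' @export
log2_group_fc <- function(table, mirna_id, group_a, group_b,
                          use_normalized = FALSE) {
  if (use_normalized && inherits(table, "pool_count_table"))
    table <- tmm_normalize(table)
  mat <- count_matrix(table)
  groups <- table_groups(table)
  if (!mirna_id %in% rownames(mat))
    mt_config_error("mirna_id", "unknown miRNA '%s'", mirna_id)
  for (g in c(group_a, group_b))
    if (!any(groups == g)) mt_config_error("group", "empty group '%s'", g)
  ma <- mean(mat[mirna_id, groups == group_a])
  mb <- mean(mat[mirna_id, groups == group_b])
  if (ma <= 0 || mb <= 0)
    mt_stop("undefined fold change for '%s': zero mean in a group", mirna_id,
            class = "mirtrend_undefined_fc")
  log2(mb / ma)
}

# Student (pooled) or Welch two-sample p-value with the degenerate
# conventions: zero variance + equal means -> 1, zero variance + different
# means -> 0.
two_sample_p <- function(x, y, var_equal = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) mt_stop("each group needs >= 2 samples")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx < .mt_eps && vy < .mt_eps)
    return(if (abs(mean(x) - mean(y)) < .mt_eps) 1 else 0)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 < .mt_eps) return(0)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2 <- vx / nx + vy / ny
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  2 * stats::pt(-abs(t), df)
}

#' Per-miRNA two-sample t-test between two groups
#'
#' Two-sided Student (pooled-variance) t-test per feature; Welch's form is
#' available behind `var_equal = FALSE`. Features with no within-group
#' variability get p = 1 when the group means coincide and p = 0 when they
#' differ (the infinite-statistic limit).
#'
#' @param table a [pool_count_table()] or [tmm_normalize()] result.
#' @param group_a,group_b group labels.
#' @param var_equal pooled-variance Student form if `TRUE` (default).
#' @return named vector of p-values, one per miRNA.
#' @export
per_mirna_ttest <- function(table, group_a, group_b, var_equal = TRUE) {
  mat <- count_matrix(table)
  groups <- table_groups(table)
  ia <- which(groups == group_a); ib <- which(groups == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    mt_stop("each group needs >= 2 samples")
  apply(mat, 1, function(x) two_sample_p(x[ib], x[ia], var_equal))
}

#' Per-miRNA one-way ANOVA across three or more groups
#'
#' One-way fixed-effects F-test per feature. Degenerate features follow the
#' documented epsilon convention: zero within-group variance yields p = 1
#' when all group means agree and p = 0 otherwise (F -> infinity limit).
#'
#' @param table a [pool_count_table()] or [tmm_normalize()] result.
#' @param groups optional subset of group labels (default: all, in the order
#'   they appear).
#' @return named vector of p-values, one per miRNA.
#' @export
per_mirna_anova <- function(table, groups = NULL) {
  mat <- count_matrix(table)
  glab <- table_groups(table)
  if (is.null(groups)) groups <- unique(glab)
  if (length(groups) < 3L)
    mt_config_error("groups", "ANOVA needs >= 3 groups")
  keep <- glab %in% groups
  mat <- mat[, keep, drop = FALSE]
  g <- factor(glab[keep], levels = groups)
  if (any(table(g) < 2L)) mt_stop("each group needs >= 2 samples")
  n <- ncol(mat); k <- length(groups)
  apply(mat, 1, function(x) {
    gm <- tapply(x, g, mean)
    ssb <- sum(tabulate(g) * (gm - mean(x))^2)
    ssw <- sum((x - gm[g])^2)
    if (ssw < .mt_eps)
      return(if (ssb < .mt_eps) 1 else 0)
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  })
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1))
    mt_config_error("p_values", "must be numeric in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Abundance filter: median reads above a threshold in at least one group
#'
#' Keeps a feature iff its median count strictly exceeds `threshold` within
#' at least one sample group (the support rule applied to stool libraries).
#'
#' @param table a [pool_count_table()].
#' @param threshold strict lower bound on the within-group median (default
#'   20 reads).
#' @return character vector of retained miRNA ids.
#' @export
filter_min_median_reads <- function(table, threshold = 20) {
  mat <- count_matrix(table)
  groups <- table_groups(table)
  check_number(threshold, "threshold")
  keep <- rep(FALSE, nrow(mat))
  for (g in unique(groups)) {
    med <- apply(mat[, groups == g, drop = FALSE], 1, stats::median)
    keep <- keep | med > threshold
  }
  rownames(mat)[keep]
}

#' Two-group comparison table for every miRNA
#'
#' Log2 fold change (b over a), two-sided t-test p-value, and BH-adjusted
#' p-value per feature. Fold changes are computed from TMM-normalised
#' values by default; `use_normalized = FALSE` switches to raw counts (the
#' scale of printed pool-average tables). Features with a zero group mean
#' get `NA` fold change.
#'
#' @param table a [pool_count_table()].
#' @param group_a,group_b group labels (baseline first).
#' @param use_normalized compute on TMM-normalised values (default).
#' @param var_equal Student (default) or Welch t-test.
#' @return data.frame: `mirna_id`, `group_a`, `group_b`, `log2_fc`,
#'   `p_value`, `fdr_adjusted_p`.
#' @export
compare_groups <- function(table, group_a, group_b, use_normalized = TRUE,
                           var_equal = TRUE) {
  if (!inherits(table, "pool_count_table"))
    mt_config_error("table", "must be a pool_count_table")
  work <- if (use_normalized) tmm_normalize(table) else table
  mat <- count_matrix(work)
  groups <- table_groups(work)
  ma <- rowMeans(mat[, groups == group_a, drop = FALSE])
  mb <- rowMeans(mat[, groups == group_b, drop = FALSE])
  fc <- ifelse(ma > 0 & mb > 0, log2(mb / ma), NA_real_)
  p <- per_mirna_ttest(work, group_a, group_b, var_equal)
  data.frame(mirna_id = rownames(mat), group_a = group_a, group_b = group_b,
             log2_fc = fc, p_value = p, fdr_adjusted_p = bh_adjust(p),
             row.names = NULL)
}
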