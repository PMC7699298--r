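# Relative qPCR quantification by the 2^-ddCt method, with single- or
# multi-reference normalisation and a replicate-level dCt comparison.

#' Construct a long-format Ct table
#'
#' @param x data.frame with columns `sample`, `condition`, `assay`,
#'   `replicate`, `ct` (cycles; positive and finite).
#' @return a validated `ct_table` data.frame.
#' @export
ct_table <- function(x) {
  need <- c("sample", "condition", "assay", "replicate", "ct")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    mt_config_error("x", "needs columns %s", paste(need, collapse = ", "))
  x <- as.data.frame(x)[need]
  if (!is.numeric(x$ct) || any(!is.finite(x$ct)) || any(x$ct <= 0))
    mt_config_error("ct", "Ct values must be positive and finite")
  class(x) <- c("ct_table", "data.frame")
  x
}

# mean Ct per (sample, assay), then per-condition target and aggregated
# reference means
condition_dct <- function(table, target_assay, reference_assays) {
  agg <- stats::aggregate(ct ~ sample + condition + assay, data = table, FUN = mean)
  conditions <- unique(table$condition)
  for (cond in conditions) {
    have <- unique(agg$assay[agg$condition == cond])
    miss <- setdiff(c(target_assay, reference_assays), have)
    if (length(miss))
      mt_stop("assay '%s' missing in condition '%s'", miss[1], cond,
              class = "mirtrend_missing_assay")
  }
  vapply(conditions, function(cond) {
    sub <- agg[agg$condition == cond, ]
    tmean <- mean(sub$ct[sub$assay == target_assay])
    # arithmetic mean of the per-assay reference Ct means (equivalent to a
    # geometric mean of the linear reference quantities)
    rmeans <- vapply(reference_assays,
                     function(a) mean(sub$ct[sub$assay == a]), numeric(1))
    tmean - mean(rmeans)
  }, numeric(1)) |> stats::setNames(conditions)
}

#' Relative expression per condition by the 2^-ddCt method
#'
#' For each condition, dCt = mean Ct(target) - mean reference Ct (replicates
#' averaged per (sample, assay) first; multiple references aggregated as the
#' arithmetic mean of their per-assay Ct means). ddCt subtracts the
#' calibrator condition's dCt, and the fold change is `2^-ddCt`, so the
#' calibrator has fold change 1 by construction.
#'
#' @param table a [ct_table()].
#' @param target_assay assay being quantified.
#' @param reference_assays one or more reference (housekeeping) assays.
#' @param calibrator_condition condition used as the 1x baseline.
#' @return data.frame: `assay`, `condition`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change`.
#' @export
delta_delta_ct <- function(table, target_assay, reference_assays,
                           calibrator_condition) {
  if (!inherits(table, "ct_table")) table <- ct_table(table)
  if (!calibrator_condition %in% table$condition)
    mt_config_error("calibrator_condition", "unknown condition '%s'",
                    calibrator_condition)
  dct <- condition_dct(table, target_assay, reference_assays)
  ddct <- dct - dct[[calibrator_condition]]
  data.frame(assay = target_assay, condition = names(dct),
             delta_ct = as.numeric(dct), delta_delta_ct = as.numeric(ddct),
             fold_change = 2^(-as.numeric(ddct)), row.names = NULL)
}

#' Compare fold changes between two conditions on replicate-level dCt
#'
#' Computes per-condition fold changes (relative to the first condition) and
#' an unpaired two-sided Student t-test on the per-sample dCt values, the
#' approximately normal scale on which qPCR comparisons are standard
#' practice. Groups with no dCt variability follow the epsilon convention
#' of [per_mirna_ttest()].
#'
#' @param table a [ct_table()].
#' @param groups pair of condition labels; the first is the baseline.
#' @param target target assay.
#' @param references one or more reference assays.
#' @param var_equal Student (default) or Welch form.
#' @return list with `fold_changes` (named, baseline = 1), `fc_ratio`
#'   (second vs first), `p_value`, and `delta_ct` (per-sample values by
#'   condition).
#' @export
compare_fc <- function(table, groups, target, references, var_equal = TRUE) {
  if (!inherits(table, "ct_table")) table <- ct_table(table)
  if (length(groups) != 2L)
    mt_config_error("groups", "must be two condition labels")
  sub <- table[table$condition %in% groups, , drop = FALSE]
  agg <- stats::aggregate(ct ~ sample + condition + assay, data = sub, FUN = mean)
  dct_sample <- function(cond) {
    s <- agg[agg$condition == cond, ]
    samples <- unique(s$sample)
    vapply(samples, function(sm) {
      rows <- s[s$sample == sm, ]
      tv <- rows$ct[rows$assay == target]
      rv <- vapply(references, function(a) {
        v <- rows$ct[rows$assay == a]
        if (!length(v))
          mt_stop("assay '%s' missing in condition '%s'", a, cond,
                  class = "mirtrend_missing_assay")
        mean(v)
      }, numeric(1))
      if (!length(tv))
        mt_stop("assay '%s' missing in condition '%s'", target, cond,
                class = "mirtrend_missing_assay")
      mean(tv) - mean(rv)
    }, numeric(1))
  }
  d1 <- dct_sample(groups[1]); d2 <- dct_sample(groups[2])
  if (length(d1) < 2L || length(d2) < 2L)
    mt_stop("each condition needs >= 2 samples")
  fc <- c(1, 2^(-(mean(d2) - mean(d1))))
  names(fc) <- groups
  list(fold_changes = fc, fc_ratio = unname(fc[2]),
       p_value = two_sample_p(d2, d1, var_equal),
       delta_ct = list(d1, d2) |> stats::setNames(groups))
}
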