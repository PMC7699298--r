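# Random-effects meta-analysis of case-control standardized mean
# differences: Hedges' g per study and the DerSimonian-Laird pooled
# estimate with a normal-quantile confidence interval.

#' Validate a table of per-study case-control summaries
#'
#' @param x data.frame with columns `study`, `n_case`, `mean_case`,
#'   `sd_case`, `n_control`, `mean_control`, `sd_control`; n >= 2 and
#'   sd > 0 per arm.
#' @return the validated data.frame with class `study_summaries`.
#' @export
as_study_summaries <- function(x) {
  need <- c("study", "n_case", "mean_case", "sd_case",
            "n_control", "mean_control", "sd_control")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    mt_config_error("x", "needs columns %s", paste(need, collapse = ", "))
  x <- as.data.frame(x)[need]
  if (anyDuplicated(x$study)) mt_config_error("study", "duplicate study ids")
  if (any(x$n_case < 2) || any(x$n_control < 2))
    mt_config_error("n", "each arm needs n >= 2")
  if (any(x$sd_case <= 0) || any(x$sd_control <= 0))
    mt_config_error("sd", "arm sds must be > 0")
  class(x) <- c("study_summaries", "data.frame")
  x
}

#' Hedges' g and its large-sample variance per study
#'
#' Bias-corrected standardized mean difference
#' `g = J * (mean_case - mean_control) / s_pooled`, with
#' `J = 1 - 3 / (4 * df - 1)`, `df = n_case + n_control - 2`, and variance
#' `(n_case + n_control) / (n_case * n_control) + g^2 / (2 (n_case +
#' n_control))`.
#'
#' @param studies a [as_study_summaries()] data.frame (one or more rows).
#' @return data.frame: `study`, `g`, `var`.
#' @export
hedges_g <- function(studies) {
  studies <- as_study_summaries(studies)
  n1 <- studies$n_case; n2 <- studies$n_control
  sp2 <- ((n1 - 1) * studies$sd_case^2 + (n2 - 1) * studies$sd_control^2) /
    (n1 + n2 - 2)
  if (any(sp2 <= 0)) mt_stop("zero pooled sd in study '%s'",
                             studies$study[which(sp2 <= 0)[1]])
  d <- (studies$mean_case - studies$mean_control) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  data.frame(study = studies$study, g = g,
             var = (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)),
             row.names = NULL)
}

# unstandardized mean-difference effect (log-FC scale when the inputs are
# log expression means)
logfc_effect <- function(studies) {
  data.frame(study = studies$study,
             g = studies$mean_case - studies$mean_control,
             var = studies$sd_case^2 / studies$n_case +
               studies$sd_control^2 / studies$n_control,
             row.names = NULL)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Moment-based between-study variance: Q from fixed-effect
#' inverse-variance weights, `tau2 = max(0, (Q - df) / C)` with
#' `C = sum(w) - sum(w^2)/sum(w)`, random-effect weights `1 / (v_i + tau2)`,
#' pooled effect = weighted mean, and a symmetric 95% CI
#' `pooled +/- 1.96 * SE`. The default effect scale is Hedges' g; set
#' `effect = "logfc"` for the unstandardized mean difference.
#'
#' @param studies a [as_study_summaries()] data.frame.
#' @param effect `"smd"` (Hedges' g, default) or `"logfc"`.
#' @return a `meta_result` list: `per_study` (study, g, var, weight),
#'   `pooled_smd`, `ci_low`, `ci_high`, `se`, `tau2`, `q_statistic`,
#'   `effect`.
#' @export
dersimonian_laird <- function(studies, effect = c("smd", "logfc")) {
  effect <- match.arg(effect)
  studies <- as_study_summaries(studies)
  if (nrow(studies) < 1L) mt_stop("need at least one study")
  es <- if (effect == "smd") hedges_g(studies) else logfc_effect(studies)
  yi <- es$g; vi <- es$var
  w <- 1 / vi
  ybar <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - ybar)^2)
  df <- length(yi) - 1
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (df > 0 && cc > 0) max(0, (q - df) / cc) else 0
  wr <- 1 / (vi + tau2)
  pooled <- sum(wr * yi) / sum(wr)
  se <- sqrt(1 / sum(wr))
  structure(list(
    per_study = data.frame(study = es$study, g = yi, var = vi,
                           weight = wr / sum(wr), row.names = NULL),
    pooled_smd = pooled, ci_low = pooled - 1.96 * se,
    ci_high = pooled + 1.96 * se, se = se, tau2 = tau2, q_statistic = q,
    effect = effect), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("random-effects meta-analysis (%s): pooled %.3f [%.3f, %.3f], tau2 %.4f, Q %.3f (k = %d)\n",
              x$effect, x$pooled_smd, x$ci_low, x$ci_high, x$tau2,
              x$q_statistic, nrow(x$per_study)))
  invisible(x)
}

#' Forest-style export table for a meta-analysis result
#'
#' @param result a [dersimonian_laird()] result.
#' @return data.frame with one row per study (g, variance, 95% CI,
#'   normalized weight) plus a final `pooled` row.
#' @export
forest_table <- function(result) {
  if (!inherits(result, "meta_result"))
    mt_config_error("result", "must be a meta_result")
  per <- result$per_study
  rows <- data.frame(study = per$study, g = per$g, var = per$var,
                     ci_low = per$g - 1.96 * sqrt(per$var),
                     ci_high = per$g + 1.96 * sqrt(per$var),
                     weight = per$weight)
  rbind(rows, data.frame(study = "pooled", g = result$pooled_smd,
                         var = result$se^2, ci_low = result$ci_low,
                         ci_high = result$ci_high, weight = 1))
}
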