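# The core screen: Jonckheere-Terpstra trend statistics over the ordered
# miRNA-activity gradient (inhibitor < control < mimic), permutation
# empirical p-values (Monte-Carlo or exact enumeration), per context and
# combined across the monolayer-to-CSC transition, and the genome-wide
# promoted/inhibited classification.

#' Construct a two-context expression study
#'
#' @param expr numeric log2 expression matrix, genes in rows and samples in
#'   columns, with dimnames.
#' @param design data.frame with columns `sample`, `context`, `treatment`,
#'   `replicate`; every sample column of `expr` must appear exactly once.
#' @param contexts ordered pair of context labels (default: order of first
#'   appearance). The first is the baseline context (e.g. monolayer), the
#'   second the derived one (e.g. CSC).
#' @param treatments declared treatment order encoding increasing miRNA
#'   activity; either three levels (inhibitor < control < mimic) or four
#'   (inhibitor < inhibitor control = mimic control < mimic).
#' @return an `expression_study` list.
#' @export
expression_study <- function(expr, design, contexts = NULL, treatments = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr) || is.null(dimnames(expr)))
    mt_config_error("expr", "must be a numeric matrix with dimnames")
  if (anyDuplicated(rownames(expr))) mt_config_error("expr", "duplicate gene ids")
  need <- c("sample", "context", "treatment", "replicate")
  if (!is.data.frame(design) || !all(need %in% names(design)))
    mt_config_error("design", "needs columns %s", paste(need, collapse = ", "))
  design <- as.data.frame(design)[need]
  miss <- setdiff(colnames(expr), design$sample)
  if (length(miss))
    mt_config_error("design", "sample(s) absent from the design: %s",
                    paste(miss, collapse = ", "))
  extra <- setdiff(design$sample, colnames(expr))
  if (length(extra))
    mt_config_error("design", "design sample(s) absent from the matrix: %s",
                    paste(extra, collapse = ", "))
  design <- design[match(colnames(expr), design$sample), ]
  if (is.null(contexts)) contexts <- unique(design$context)
  if (length(contexts) != 2L || !setequal(contexts, unique(design$context)))
    mt_config_error("contexts", "must be the two context labels of the design")
  if (is.null(treatments)) {
    treatments <- if (all(unique(design$treatment) %in%
                          c("inhibitor", "control", "mimic")))
      c("inhibitor", "control", "mimic")
    else unique(design$treatment)
  }
  if (!setequal(treatments, unique(design$treatment)) ||
      !length(treatments) %in% c(3L, 4L))
    mt_config_error("treatments",
                    "must order the design's 3 or 4 treatment levels")
  cells <- table(design$context, design$treatment)
  if (any(cells < 2L))
    mt_config_error("design",
                    "every (context, treatment) cell needs >= 2 replicates")
  structure(list(expr = expr, design = design, contexts = contexts,
                 treatments = treatments),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$expr), "genes x", ncol(x$expr), "samples;",
      "contexts:", paste(x$contexts, collapse = " -> "), "; treatments:",
      paste(x$treatments, collapse = " < "), "\n")
  invisible(x)
}

# Ordered treatment codes. Three levels map to 1 < 2 < 3. Four levels (the
# two control arms distinct in the design) map to 1 < 2 = 2 < 3 whether the
# controls are pooled (arms = "three") or kept as tied levels
# (arms = "four"): for the JT statistic the two readings coincide by
# construction, since tied group codes and a pooled group count the same
# cross-group pairs.
treatment_codes <- function(study, arms = c("three", "four")) {
  arms <- match.arg(arms)
  tr <- study$treatments
  pos <- match(study$design$treatment, tr)
  if (length(tr) == 3L) pos else c(1L, 2L, 2L, 3L)[pos]
}

group_codes <- function(groups) {
  if (is.factor(groups)) return(as.integer(groups))
  if (is.numeric(groups)) return(match(groups, sort(unique(groups))))
  mt_config_error("groups", "must be a factor (ordered by levels) or numeric codes")
}

# plain JT for one labelling: sum over ordered group pairs of
# #(x in a < y in b) + 1/2 #(ties)
jt_direct <- function(x, gi) {
  u <- sort(unique(gi))
  s <- 0
  for (a in seq_len(length(u) - 1L)) {
    xa <- x[gi == u[a]]
    for (b in seq(a + 1L, length(u))) {
      xb <- x[gi == u[b]]
      s <- s + sum(outer(xa, xb, "<")) + 0.5 * sum(outer(xa, xb, "=="))
    }
  }
  s
}

# index pairs (p, q) of sample positions with group(p) ordered before
# group(q); used to evaluate JT over many permutations at once
jt_pairs <- function(gi) {
  u <- sort(unique(gi))
  ps <- list(); qs <- list()
  for (a in seq_len(length(u) - 1L)) for (b in seq(a + 1L, length(u))) {
    eg <- expand.grid(which(gi == u[a]), which(gi == u[b]))
    ps[[length(ps) + 1L]] <- eg[[1L]]
    qs[[length(qs) + 1L]] <- eg[[2L]]
  }
  list(p = unlist(ps), q = unlist(qs))
}

jt_from_perms <- function(values, P, pairs) {
  X <- matrix(values[P], nrow(P))
  A <- X[, pairs$p, drop = FALSE]
  B <- X[, pairs$q, drop = FALSE]
  rowSums(A < B) + 0.5 * rowSums(A == B)
}

#' Jonckheere-Terpstra statistic for ordered groups
#'
#' `JT = sum` over ordered group pairs (a before b) of the number of pairs
#' `x in a, y in b` with `x < y`, counting ties as 1/2.
#'
#' @param values numeric observations.
#' @param groups ordered group assignment: a factor whose level order is the
#'   trend order, or numeric codes ordered numerically.
#' @return the JT statistic (a single number).
#' @export
jt_statistic <- function(values, groups) {
  gi <- group_codes(groups)
  if (length(values) != length(gi))
    mt_config_error("groups", "length must match 'values'")
  if (length(unique(gi)) < 2L)
    mt_stop("JT needs at least 2 ordered groups")
  jt_direct(values, gi)
}

# exact enumeration over all distinguishable label arrangements; with
# `blocks`, arrangements are enumerated independently within each block
# (context-stratified exact test)
jt_exact_p <- function(values, gi, direction, blocks = NULL, cap = 250000) {
  if (is.null(blocks)) blocks <- rep(1L, length(gi))
  ub <- unique(blocks)
  per_block <- lapply(ub, function(b) {
    pos <- which(blocks == b)
    codes <- sort(unique(gi[pos]))
    counts <- vapply(codes, function(k) sum(gi[pos] == k), integer(1))
    list(pos = pos, codes = codes,
         arr = NULL, counts = counts)
  })
  total <- prod(vapply(per_block, function(bl) n_multiset_perms(bl$counts),
                       numeric(1)))
  if (total > cap)
    mt_stop("exact mode infeasible: %.0f distinguishable assignments (cap %d)",
            total, cap)
  for (i in seq_along(per_block)) {
    bl <- per_block[[i]]
    arr <- multiset_permutations(bl$counts)     # codes as 1..K within block
    per_block[[i]]$arr <- matrix(bl$codes[arr], nrow(arr))
  }
  obs <- jt_direct(values, gi)
  lab <- gi
  count_extreme <- function(i) {
    if (i > length(per_block)) {
      jt <- jt_direct(values, lab)
      return(if (direction == "increasing") (jt >= obs - 1e-9)
             else (jt <= obs + 1e-9))
    }
    bl <- per_block[[i]]
    tot <- 0
    for (r in seq_len(nrow(bl$arr))) {
      lab[bl$pos] <<- bl$arr[r, ]
      tot <- tot + count_extreme(i + 1L)
    }
    tot
  }
  b <- count_extreme(1L)
  list(p = b / total, obs = obs, n_assignments = total)
}

# Monte-Carlo permutation p from the current RNG stream
jt_mc_p <- function(values, gi, direction, n_perm, blocks = NULL,
                    pairs = NULL) {
  if (is.null(pairs)) pairs <- jt_pairs(gi)
  P <- if (is.null(blocks)) rand_perm_rows(n_perm, length(values))
       else stratified_perms(blocks, n_perm)
  jt <- jt_from_perms(values, P, pairs)
  obs <- jt_direct(values, gi)
  b <- if (direction == "increasing") sum(jt >= obs - 1e-9)
       else sum(jt <= obs + 1e-9)
  list(p = (b + 1) / (n_perm + 1), obs = obs, perms = jt)
}

#' Permutation empirical p-value for the JT trend test
#'
#' One-sided empirical p in the stated direction. Monte-Carlo mode permutes
#' the group labels `n_perm` times and applies the add-one rule
#' `p = (b + 1) / (n_perm + 1)`, so p is never exactly zero. Exact mode
#' enumerates all distinguishable label assignments and returns the exact
#' tail proportion (the observed assignment counts itself, so exact p >= 1
#' / #assignments).
#'
#' @param values numeric observations.
#' @param groups ordered group assignment (see [jt_statistic()]).
#' @param direction `"increasing"` or `"decreasing"` alternative.
#' @param n_perm number of Monte-Carlo permutations (>= 1; values below 100
#'   trigger a warning). Ignored in exact mode.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param exact enumerate all assignments instead of sampling.
#' @return the empirical p-value, with attributes `statistic` (observed JT)
#'   and, in exact mode, `n_assignments`.
#' @export
jt_permutation_p <- function(values, groups,
                             direction = c("increasing", "decreasing"),
                             n_perm = 10000, seed = NULL, exact = FALSE) {
  direction <- match.arg(direction)
  gi <- group_codes(groups)
  if (length(unique(gi)) < 2L)
    mt_stop("JT needs at least 2 ordered groups")
  if (exact) {
    res <- jt_exact_p(values, gi, direction)
    return(structure(res$p, statistic = res$obs,
                     n_assignments = res$n_assignments))
  }
  if (n_perm < 1) mt_config_error("n_perm", "must be >= 1")
  if (n_perm < 100)
    warning("n_perm < 100: empirical p-values will be very coarse")
  if (!is.null(seed)) set.seed(seed)
  res <- jt_mc_p(values, gi, direction, n_perm)
  structure(res$p, statistic = res$obs)
}

#' Classify a gene as promoted or inhibited by the miRNA
#'
#' Direction of association between the ordered treatment gradient and
#' expression, pooled across contexts: the sign of the Spearman rank
#' correlation between treatment order (inhibitor = 1, control = 2,
#' mimic = 3) and expression. Positive -> `"promoted"` (the miRNA raises
#' the gene), negative -> `"inhibited"`; an exactly zero correlation is
#' broken toward `"promoted"`. A flat gene (all values equal) returns
#' `"degenerate"` and is excluded from screening.
#'
#' @param study an [expression_study()].
#' @param gene_id gene to classify.
#' @return one of `"promoted"`, `"inhibited"`, `"degenerate"`.
#' @export
classify_direction <- function(study, gene_id) {
  x <- study_gene(study, gene_id)
  direction_of(x, treatment_codes(study))
}

study_gene <- function(study, gene_id) {
  if (!inherits(study, "expression_study"))
    mt_config_error("study", "must be an expression_study")
  if (!gene_id %in% rownames(study$expr))
    mt_config_error("gene_id", "unknown gene '%s'", gene_id)
  study$expr[gene_id, ]
}

direction_of <- function(x, codes) {
  if (stats::sd(x) == 0) return("degenerate")
  rho <- suppressWarnings(stats::cor(codes, x, method = "spearman"))
  if (is.na(rho) || rho >= 0) "promoted" else "inhibited"
}

#' Combined monolayer-to-CSC transition trend
#'
#' JT trend over six ordered groups laid out context-major (first context's
#' inhibitor, control, mimic, then the second context's), testing the
#' monotone increasing alternative for promoted genes and the monotone
#' decreasing alternative on the same layout for inhibited genes.
#'
#' Two permutation nulls are available. The default `"stratified"` shuffles
#' treatment labels within each context independently, preserving the
#' context blocking of the design; because every first-context group
#' precedes every second-context group, the cross-context pair counts are
#' then invariant under permutation and the test pools the evidence of the
#' two within-context trends (between-context level shifts are blocked
#' out). The `"unstratified"` null shuffles all labels jointly, so the test
#' additionally demands a progressive ordering across the
#' monolayer-to-CSC transition: a gene trending within both contexts but
#' with CSC levels falling back below the monolayer maximum loses
#' significance under this null. Exact mode enumerates all distinguishable
#' assignments (jointly per context when stratified).
#'
#' @param study an [expression_study()] with both contexts present.
#' @param gene_id gene to test.
#' @param direction `"promoted"` (increasing) or `"inhibited"`
#'   (decreasing); defaults to the fitted [classify_direction()].
#' @param n_perm Monte-Carlo permutations.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param exact exact enumeration instead of sampling.
#' @param arms treatment-arm handling, see [trend_screen()].
#' @param null `"stratified"` (default) or `"unstratified"` permutation
#'   null, see Details.
#' @return empirical p-value with attribute `statistic`.
#' @export
combined_transition_trend <- function(study, gene_id, direction = NULL,
                                      n_perm = 10000, seed = NULL,
                                      exact = FALSE,
                                      arms = c("three", "four"),
                                      null = c("stratified", "unstratified")) {
  arms <- match.arg(arms)
  null <- match.arg(null)
  x <- study_gene(study, gene_id)
  trt <- treatment_codes(study, arms)
  ctx <- match(study$design$context, study$contexts)
  if (any(is.na(ctx)) || length(unique(ctx)) != 2L)
    mt_stop("both contexts must be present")
  gi <- (ctx - 1L) * max(trt) + trt
  dir <- if (is.null(direction)) direction_of(x, trt) else
    match.arg(direction, c("promoted", "inhibited"))
  if (dir == "degenerate")
    mt_stop("flat gene '%s': no direction", gene_id)
  alt <- if (dir == "promoted") "increasing" else "decreasing"
  blocks <- if (null == "stratified") ctx else NULL
  if (exact) {
    res <- jt_exact_p(x, gi, alt, blocks = blocks)
    return(structure(res$p, statistic = res$obs,
                     n_assignments = res$n_assignments))
  }
  if (n_perm < 1) mt_config_error("n_perm", "must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  res <- jt_mc_p(x, gi, alt, n_perm, blocks = blocks)
  structure(res$p, statistic = res$obs)
}

#' Genome-wide trend screen for miRNA-promoted and -inhibited genes
#'
#' For every gene: fits the regulation direction (pooled across contexts),
#' computes one-sided JT permutation p-values in that direction within each
#' context and combined across the monolayer-to-CSC transition, and flags
#' the gene as consistent with the working hypothesis iff its fitted
#' direction is identical in both contexts and both per-context trends are
#' significant at `alpha` (after the selected multiple-testing treatment).
#'
#' Multiple-testing modes: `"bh"` (default) applies Benjamini-Hochberg
#' across genes within each context; `"none"` uses raw empirical p;
#' `"maxt"` applies Westfall-Young max-T family-wise correction, with all
#' genes sharing one permutation stream (in that mode the raw per-gene p is
#' computed from the shared stream too). For `"bh"` and `"none"`, each
#' gene's permutations come from a child stream keyed by the gene id, so
#' per-gene results are reproducible independently of gene order.
#'
#' @param study an [expression_study()].
#' @param gene_list optional curated gene ids to intersect with the hits.
#' @param alpha per-context significance level.
#' @param n_perm permutations per test.
#' @param seed run seed (recorded in the summary).
#' @param correction `"bh"`, `"none"`, or `"maxt"`.
#' @param arms `"three"` pools the two control arms of a four-arm design
#'   into one control level; `"four"` keeps them as tied levels (the JT
#'   statistic coincides by construction).
#' @return data.frame of per-gene results (one row per gene: direction,
#'   per-context and combined JT statistics and empirical p, adjusted p,
#'   consistency flag, curated membership) with a `summary` attribute
#'   (stage counts and run parameters).
#' @export
trend_screen <- function(study, gene_list = NULL, alpha = 0.05,
                         n_perm = 10000, seed = 1L,
                         correction = c("bh", "none", "maxt"),
                         arms = c("three", "four")) {
  correction <- match.arg(correction)
  arms <- match.arg(arms)
  if (!inherits(study, "expression_study"))
    mt_config_error("study", "must be an expression_study")
  check_number(alpha, "alpha", 0, 1)
  n_perm <- check_count(n_perm, "n_perm")
  trt <- treatment_codes(study, arms)
  ctx <- match(study$design$context, study$contexts)
  i1 <- which(ctx == 1L); i2 <- which(ctx == 2L)
  gi1 <- trt[i1]; gi2 <- trt[i2]
  gi_full <- (ctx - 1L) * max(trt) + trt
  pairs1 <- jt_pairs(gi1); pairs2 <- jt_pairs(gi2)
  pairs_full <- jt_pairs(gi_full)
  genes <- rownames(study$expr)
  G <- length(genes)
  out <- data.frame(
    gene_id = genes, direction = NA_character_,
    direction_monolayer = NA_character_, direction_csc = NA_character_,
    jt_mono = NA_real_, jt_csc = NA_real_, jt_combined = NA_real_,
    p_trend_mono = NA_real_, p_trend_csc = NA_real_, p_trend = NA_real_,
    adj_p_mono = NA_real_, adj_p_csc = NA_real_,
    consistent_with_hypothesis = FALSE, degenerate = FALSE,
    row.names = NULL)
  flat <- apply(study$expr, 1, function(x) stats::sd(x) == 0)
  out$degenerate <- unname(flat)
  live <- which(!flat)
  if (!length(live))
    warning("all genes are flat; empty screen result")
  dirs <- vapply(live, function(g) direction_of(study$expr[g, ], trt), "")
  out$direction[live] <- dirs
  out$direction_monolayer[live] <-
    vapply(live, function(g) direction_of(study$expr[g, i1], gi1), "")
  out$direction_csc[live] <-
    vapply(live, function(g) direction_of(study$expr[g, i2], gi2), "")
  if (correction == "maxt") {
    set.seed(child_seed(seed, 0))
    P1 <- rand_perm_rows(n_perm, length(i1))
    P2 <- rand_perm_rows(n_perm, length(i2))
    Pf <- stratified_perms(ctx, n_perm)
    s1 <- matrix(NA_real_, n_perm, G); s2 <- matrix(NA_real_, n_perm, G)
    o1 <- rep(NA_real_, G); o2 <- rep(NA_real_, G)
    for (g in live) {
      x <- study$expr[g, ]
      sgn <- if (out$direction[g] == "promoted") 1 else -1
      j1 <- jt_from_perms(x[i1], P1, pairs1)
      j2 <- jt_from_perms(x[i2], P2, pairs2)
      out$jt_mono[g] <- jt_direct(x[i1], gi1)
      out$jt_csc[g] <- jt_direct(x[i2], gi2)
      s1[, g] <- sgn * (j1 - mean(j1)) / max(stats::sd(j1), .mt_eps)
      s2[, g] <- sgn * (j2 - mean(j2)) / max(stats::sd(j2), .mt_eps)
      o1[g] <- sgn * (out$jt_mono[g] - mean(j1)) / max(stats::sd(j1), .mt_eps)
      o2[g] <- sgn * (out$jt_csc[g] - mean(j2)) / max(stats::sd(j2), .mt_eps)
      out$p_trend_mono[g] <- (sum(s1[, g] >= o1[g] - 1e-9) + 1) / (n_perm + 1)
      out$p_trend_csc[g] <- (sum(s2[, g] >= o2[g] - 1e-9) + 1) / (n_perm + 1)
      jf <- jt_from_perms(x, Pf, pairs_full)
      of <- jt_direct(x, gi_full)
      bf <- if (out$direction[g] == "promoted") sum(jf >= of - 1e-9)
            else sum(jf <= of + 1e-9)
      out$jt_combined[g] <- of
      out$p_trend[g] <- (bf + 1) / (n_perm + 1)
    }
    max1 <- apply(s1[, live, drop = FALSE], 1, max)
    max2 <- apply(s2[, live, drop = FALSE], 1, max)
    out$adj_p_mono[live] <- vapply(live, function(g)
      (sum(max1 >= o1[g] - 1e-9) + 1) / (n_perm + 1), numeric(1))
    out$adj_p_csc[live] <- vapply(live, function(g)
      (sum(max2 >= o2[g] - 1e-9) + 1) / (n_perm + 1), numeric(1))
  } else {
    for (g in live) {
      x <- study$expr[g, ]
      alt <- if (out$direction[g] == "promoted") "increasing" else "decreasing"
      set.seed(child_seed(seed, hash_id(genes[g])))
      r1 <- jt_mc_p(x[i1], gi1, alt, n_perm, pairs = pairs1)
      r2 <- jt_mc_p(x[i2], gi2, alt, n_perm, pairs = pairs2)
      rf <- jt_mc_p(x, gi_full, alt, n_perm, blocks = ctx, pairs = pairs_full)
      out$jt_mono[g] <- r1$obs; out$p_trend_mono[g] <- r1$p
      out$jt_csc[g] <- r2$obs; out$p_trend_csc[g] <- r2$p
      out$jt_combined[g] <- rf$obs; out$p_trend[g] <- rf$p
    }
    if (correction == "bh") {
      out$adj_p_mono[live] <- bh_adjust(out$p_trend_mono[live])
      out$adj_p_csc[live] <- bh_adjust(out$p_trend_csc[live])
    }
  }
  p_use_m <- if (correction == "none") out$p_trend_mono else out$adj_p_mono
  p_use_c <- if (correction == "none") out$p_trend_csc else out$adj_p_csc
  same_dir <- !out$degenerate &
    out$direction_monolayer == out$direction_csc
  out$consistent_with_hypothesis <- same_dir &
    !is.na(p_use_m) & p_use_m <= alpha & !is.na(p_use_c) & p_use_c <= alpha
  out$in_curated <- if (is.null(gene_list)) NA else out$gene_id %in% gene_list
  summary <- list(
    n_genes = G, n_degenerate = sum(out$degenerate),
    n_direction_consistent = sum(same_dir, na.rm = TRUE),
    n_consistent_with_hypothesis = sum(out$consistent_with_hypothesis),
    n_curated = if (is.null(gene_list)) NA_integer_ else length(gene_list),
    n_consistent_in_curated = if (is.null(gene_list)) NA_integer_ else
      sum(out$consistent_with_hypothesis & out$in_curated),
    alpha = alpha, n_perm = n_perm, seed = seed,
    correction = correction, arms = arms)
  attr(out, "summary") <- summary
  class(out) <- c("trend_screen_result", "data.frame")
  out
}

#' @export
print.trend_screen_result <- function(x, ...) {
  s <- attr(x, "summary")
  if (is.null(s)) return(NextMethod())   # subsets drop the summary
  cat(sprintf(paste0("trend screen: %d genes (%d degenerate), %d same-direction,",
                     " %d consistent with the working hypothesis\n",
                     "alpha %.3g, n_perm %d, seed %s, correction %s, arms %s\n"),
              s$n_genes, s$n_degenerate, s$n_direction_consistent,
              s$n_consistent_with_hypothesis, s$alpha, s$n_perm,
              format(s$seed), s$correction, s$arms))
  if (!is.na(s$n_curated))
    cat(sprintf("curated list: %d genes, %d consistent hits in it\n",
                s$n_curated, s$n_consistent_in_curated))
  n_show <- min(nrow(x), 6L)
  if (n_show > 0L) {
    print(utils::head(as.data.frame(x), n_show))
    if (nrow(x) > n_show) cat("... and", nrow(x) - n_show, "more genes\n")
  }
  invisible(x)
}

#' Ranking metric for enrichment from a screen result
#'
#' Signed `-log10` of the combined transition empirical p-value, positive
#' for promoted genes and negative for inhibited ones, sorted decreasing
#' (strongest promoted first). Degenerate genes are dropped.
#'
#' @param result a [trend_screen()] result.
#' @param p_column which empirical p to use (default the combined
#'   `"p_trend"`; any p column of the result is accepted).
#' @return data.frame `gene_id`, `score`, ordered by decreasing score.
#' @export
screen_ranking <- function(result, p_column = "p_trend") {
  if (!inherits(result, "trend_screen_result"))
    mt_config_error("result", "must be a trend_screen_result")
  if (!p_column %in% names(result) || !is.numeric(result[[p_column]]))
    mt_config_error("p_column", "unknown p column '%s'", p_column)
  keep <- !result$degenerate & !is.na(result[[p_column]])
  sgn <- ifelse(result$direction[keep] == "promoted", 1, -1)
  score <- sgn * -log10(result[[p_column]][keep])
  ord <- order(score, decreasing = TRUE)
  data.frame(gene_id = result$gene_id[keep][ord], score = score[ord],
             row.names = NULL)
}
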