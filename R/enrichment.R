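# Weighted Kolmogorov-Smirnov (GSEA-style) gene-set enrichment over a
# ranked gene list, with gene-label or sample permutation nulls.

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranking top to bottom keeping a running sum that increases by
#' `|score|^weight_exponent / sum over set members of |score|^exponent` at
#' set members and decreases by `1 / (N - |set|)` elsewhere; the enrichment
#' score is the signed maximum deviation from zero. `weight_exponent = 0`
#' gives the classical (unweighted) KS form; the default 1 is the standard
#' weighting of the method. If every set member has zero score the
#' increments fall back to the unweighted form.
#'
#' @param ranked_genes gene ids ordered from highest to lowest score.
#' @param scores ranking scores aligned with `ranked_genes` (finite).
#' @param gene_set character vector of member gene ids.
#' @param weight_exponent non-negative weighting exponent.
#' @return list with `es`, `running_sum` (length N), and `leading_edge`
#'   (the set members at or before the extremum for positive ES, at or
#'   after it for negative ES).
#' @export
weighted_ks_es <- function(ranked_genes, scores, gene_set,
                           weight_exponent = 1) {
  N <- length(ranked_genes)
  if (length(scores) != N)
    mt_config_error("scores", "must align with 'ranked_genes'")
  if (any(!is.finite(scores))) mt_config_error("scores", "must be finite")
  if (anyDuplicated(ranked_genes))
    mt_config_error("ranked_genes", "duplicate gene ids in the ranking")
  check_number(weight_exponent, "weight_exponent", 0)
  hit <- ranked_genes %in% gene_set
  m <- sum(hit)
  if (m == 0L) mt_stop("gene set does not intersect the ranked universe")
  if (m == N) mt_stop("gene set covers the whole universe; decrement undefined")
  es_from_hits(which(hit), abs(scores)^weight_exponent, N,
               ranked_genes = ranked_genes)
}

# core running-sum evaluation given hit positions and |score|^p weights
es_from_hits <- function(hit_pos, w, N, ranked_genes = NULL) {
  m <- length(hit_pos)
  wh <- w[hit_pos]
  tot <- sum(wh)
  inc <- numeric(N)
  inc[hit_pos] <- if (tot > 0) wh / tot else 1 / m
  dec <- rep.int(1 / (N - m), N)
  dec[hit_pos] <- 0
  rs <- cumsum(inc - dec)
  i <- which.max(abs(rs))
  es <- rs[i]
  le <- NULL
  if (!is.null(ranked_genes)) {
    le <- if (es >= 0) ranked_genes[hit_pos[hit_pos <= i]]
          else ranked_genes[hit_pos[hit_pos >= i]]
  }
  list(es = es, running_sum = rs, leading_edge = le)
}

#' Permutation empirical p-value for a weighted-KS enrichment score
#'
#' Two modes. `"gene_label"` (default) permutes the set membership over the
#' ranked universe, keeping the ranking fixed; with `exact = TRUE` it
#' enumerates all `choose(N, m)` memberships instead of sampling.
#' `"sample"` recomputes the ranking itself under permuted designs:
#' `ranking_generator(i)` must return a list with `ranked_genes` and
#' `scores` for the i-th permuted dataset (typically produced by re-running
#' the trend screen on permuted treatment labels). Both modes count
#' permutations with `|ES|` at least as extreme as observed; Monte-Carlo
#' p-values use the add-one rule.
#'
#' @param ranked_genes,scores,gene_set,weight_exponent as in
#'   [weighted_ks_es()].
#' @param n_perm number of permutations.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param mode `"gene_label"` or `"sample"`.
#' @param exact gene-label mode only: enumerate all memberships.
#' @param ranking_generator sample mode only: function of the permutation
#'   index returning `list(ranked_genes =, scores =)`.
#' @return empirical p-value with attribute `es` (the observed score).
#' @export
enrichment_p <- function(ranked_genes, scores, gene_set, n_perm = 10000,
                         seed = NULL, mode = c("gene_label", "sample"),
                         weight_exponent = 1, exact = FALSE,
                         ranking_generator = NULL) {
  mode <- match.arg(mode)
  obs <- weighted_ks_es(ranked_genes, scores, gene_set, weight_exponent)
  N <- length(ranked_genes)
  m <- sum(ranked_genes %in% gene_set)
  w <- abs(scores)^weight_exponent
  if (mode == "gene_label" && exact) {
    if (choose(N, m) > 250000)
      mt_stop("exact mode infeasible: choose(%d, %d) memberships", N, m)
    combos <- utils::combn(N, m)
    es_all <- apply(combos, 2, function(idx) es_from_hits(idx, w, N)$es)
    b <- sum(abs(es_all) >= abs(obs$es) - 1e-12)
    return(structure(b / ncol(combos), es = obs$es))
  }
  if (n_perm < 1) mt_config_error("n_perm", "must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  es_perm <- numeric(n_perm)
  if (mode == "gene_label") {
    for (r in seq_len(n_perm))
      es_perm[r] <- es_from_hits(sort(sample.int(N, m)), w, N)$es
  } else {
    if (!is.function(ranking_generator))
      mt_config_error("ranking_generator",
                      "sample mode needs a ranking_generator function")
    for (r in seq_len(n_perm)) {
      rk <- ranking_generator(r)
      es_perm[r] <- weighted_ks_es(rk$ranked_genes, rk$scores, gene_set,
                                   weight_exponent)$es
    }
  }
  b <- sum(abs(es_perm) >= abs(obs$es) - 1e-12)
  structure((b + 1) / (n_perm + 1), es = obs$es)
}

#' Enrichment of screen hits in each gene set of a collection
#'
#' Ranks genes by the screen's signed significance metric (see
#' [screen_ranking()]) and evaluates each gene set's weighted-KS enrichment
#' score with a gene-label permutation empirical p-value.
#'
#' @param result a [trend_screen()] result.
#' @param gene_sets a [read_gmt()] collection (named list of id vectors).
#' @param n_perm permutations per set.
#' @param seed integer seed (each set gets a child stream keyed by its
#'   name, so results do not depend on set order).
#' @param weight_exponent weighting exponent.
#' @param min_overlap drop sets whose overlap with the ranked universe is
#'   below this (default 1).
#' @return data.frame: `set`, `size`, `overlap`, `es`, `empirical_p`,
#'   `leading_edge` (comma-separated ids).
#' @export
enrich_screen <- function(result, gene_sets, n_perm = 10000, seed = 1L,
                          weight_exponent = 1, min_overlap = 1) {
  rk <- screen_ranking(result)
  sets <- if (inherits(gene_sets, "gene_set_collection")) gene_sets$sets
          else gene_sets
  if (!length(sets) || is.null(names(sets)))
    mt_config_error("gene_sets", "must be a named list of gene-id vectors")
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], rk$gene_id)
    if (length(members) < min_overlap || length(members) == nrow(rk))
      return(NULL)
    es <- weighted_ks_es(rk$gene_id, rk$score, members, weight_exponent)
    p <- enrichment_p(rk$gene_id, rk$score, members, n_perm = n_perm,
                      seed = child_seed(seed, hash_id(nm)),
                      weight_exponent = weight_exponent)
    data.frame(set = nm, size = length(sets[[nm]]),
               overlap = length(members), es = es$es,
               empirical_p = as.numeric(p),
               leading_edge = paste(es$leading_edge, collapse = ","),
               row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no gene set overlaps the ranked universe")
    return(data.frame(set = character(), size = integer(),
                      overlap = integer(), es = numeric(),
                      empirical_p = numeric(), leading_edge = character()))
  }
  do.call(rbind, rows)
}
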