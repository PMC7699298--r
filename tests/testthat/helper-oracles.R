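# Independent oracles and fixture builders shared across the suite.

# JT via R's Mann-Whitney machinery: wilcox.test(xb, xa)$statistic counts
# pairs with xb > xa (ties as 1/2), so summing it over ordered group pairs
# (later group as first argument) reproduces the JT definition through a
# code path independent of the package's.
oracle_jt <- function(x, gi) {
  u <- sort(unique(gi))
  s <- 0
  for (a in seq_len(length(u) - 1L)) {
    for (b in seq(a + 1L, length(u))) {
      w <- suppressWarnings(
        stats::wilcox.test(x[gi == u[b]], x[gi == u[a]], exact = FALSE))
      s <- s + unname(w$statistic)
    }
  }
  s
}

# all n! permutations of 1..n (insertion construction)
all_value_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_value_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k), deparse.level = 0)))
}

# exact one-sided JT permutation p by brute force over all value
# permutations (equivalent to enumerating label assignments, with each
# distinguishable assignment weighted equally)
oracle_exact_jt_p <- function(x, gi, direction = "increasing",
                              blocks = NULL) {
  obs <- oracle_jt(x, gi)
  n <- length(x)
  if (is.null(blocks)) {
    P <- all_value_perms(n)
  } else {
    # block-wise permutations: cartesian product of within-block orders
    ub <- unique(blocks)
    parts <- lapply(ub, function(b) {
      pos <- which(blocks == b)
      apply(all_value_perms(length(pos)), 1, function(o) pos[o],
            simplify = FALSE)
    })
    grid <- expand.grid(lapply(parts, seq_along))
    P <- t(apply(grid, 1, function(row) {
      idx <- integer(n)
      for (j in seq_along(ub))
        idx[which(blocks == ub[j])] <- parts[[j]][[row[j]]]
      idx
    }))
  }
  jts <- apply(P, 1, function(idx) oracle_jt(x[idx], gi))
  if (direction == "increasing") mean(jts >= obs - 1e-9)
  else mean(jts <= obs + 1e-9)
}

# expression study built from explicit per-cell means:
# means[[context]][treatment] ; replicates per cell; optional noise
toy_study <- function(mono_means, csc_means, reps = 2, noise_sd = 0,
                      seed = 1, jitter = NULL) {
  treatments <- c("inhibitor", "control", "mimic")
  design <- expand.grid(replicate = seq_len(reps), treatment = treatments,
                        context = c("monolayer", "CSC"),
                        stringsAsFactors = FALSE)[, c("context", "treatment",
                                                      "replicate")]
  design$sample <- paste(design$context, design$treatment, design$replicate,
                         sep = "_")
  mu <- ifelse(design$context == "monolayer",
               mono_means[match(design$treatment, treatments)],
               csc_means[match(design$treatment, treatments)])
  set.seed(seed)
  x <- mu + stats::rnorm(length(mu), 0, noise_sd)
  if (!is.null(jitter)) x <- x + jitter  # deterministic within-cell spread
  expr <- matrix(x, 1, length(x), dimnames = list("g1", design$sample))
  expression_study(expr, design)
}

# small deterministic within-cell offsets so noiseless cells are not tied
cell_jitter <- function(reps, n_cells = 6, scale = 0.01) {
  rep(seq_len(reps) * scale, n_cells)
}
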