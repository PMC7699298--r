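# Internal helpers: classed errors, argument checks, seed fan-out,
# permutation machinery shared by the trend and enrichment modules.

mt_stop <- function(msg, ..., class = "mirtrend_error") {
  txt <- if (...length() > 0L) sprintf(msg, ...) else msg
  stop(errorCondition(txt, class = c(class, "mirtrend_error")))
}

mt_config_error <- function(field, msg, ...) {
  mt_stop(paste0("invalid configuration field '", field, "': ", sprintf(msg, ...)),
          class = "mirtrend_config_error")
}

mt_parse_error <- function(file, msg, ...) {
  mt_stop(paste0("parse error in '", file, "': ", sprintf(msg, ...)),
          class = "mirtrend_parse_error")
}

check_number <- function(x, field, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    mt_config_error(field, "must be a single finite number")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    mt_config_error(field, "must be in %s%s, %s]",
                    if (strict_lower) "(" else "[", lower, upper)
  x
}

check_count <- function(x, field, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < lower)
    mt_config_error(field, "must be an integer >= %d", lower)
  as.integer(x)
}

# Zero-variance epsilon used by the degenerate-test conventions: two groups
# with no within-group variability get p = 1 when their means coincide and
# p = 0 when they differ (the infinite-statistic limit).
.mt_eps <- 1e-12

# --- seed fan-out -----------------------------------------------------------

# One run seed fans out to per-generator / per-gene child seeds through a
# fixed affine map modulo a prime below 2^31, so partial re-runs and
# reordered inputs reproduce bit-identical results.
child_seed <- function(seed, stream) {
  # exact in double arithmetic: 97561 * (2^31 - 1) < 2^53
  (as.double(seed) %% 2147483629 + 97561 * (as.double(stream) %% 2147483629)) %% 2147483629
}

# Small deterministic string hash, used to key per-gene permutation streams
# by gene id (stable under gene reordering).
hash_id <- function(x) {
  vapply(as.character(x), function(s) {
    h <- 0
    for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483629
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# --- permutation machinery --------------------------------------------------

# n_perm random permutations of 1..nb, one per row, drawn from the current
# RNG stream with a single order() call (row-major random-key sort).
rand_perm_rows <- function(n_perm, nb) {
  if (nb == 1L) return(matrix(1L, n_perm, 1L))
  u <- stats::runif(n_perm * nb)
  ri <- rep.int(seq_len(n_perm), nb)
  ci <- rep(seq_len(nb), each = n_perm)
  matrix(ci[order(ri, u)], n_perm, nb, byrow = TRUE)
}

# Permutations of sample positions restricted to blocks (labels are shuffled
# within each block only). Rows index permutations; entry [r, j] is the
# sample whose value occupies position j in permutation r.
stratified_perms <- function(blocks, n_perm) {
  n <- length(blocks)
  P <- matrix(rep(seq_len(n), each = n_perm), n_perm, n)
  for (b in unique(blocks)) {
    pos <- which(blocks == b)
    P[, pos] <- matrix(pos[rand_perm_rows(n_perm, length(pos))], n_perm)
  }
  P
}

# All distinguishable arrangements of a label multiset given per-group
# counts; one row per arrangement, entries are group codes.
multiset_permutations <- function(counts) {
  n <- sum(counts)
  if (n == 0L) return(matrix(integer(0), 1L, 0L))
  out <- vector("list", sum(counts > 0L))
  j <- 0L
  for (g in which(counts > 0L)) {
    c2 <- counts
    c2[g] <- c2[g] - 1L
    rest <- multiset_permutations(c2)
    j <- j + 1L
    out[[j]] <- cbind(rep.int(g, nrow(rest)), rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

n_multiset_perms <- function(counts) {
  exp(lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)))
}
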