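# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use different code paths from the package:
# brute-force enumeration, O(m^2) scans, stats:: reference routines.

# Spearman rho as plain Pearson on average ranks (the textbook definition).
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# O(m^2) Benjamini-Hochberg: q_i = min over j with p_j >= p_i of
# (m / rank_j) * p_j, capped at 1. Ranks of tied p-values are assigned by
# sorted position; the min picks the largest tied rank either way.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  rk <- integer(m)
  rk[o] <- seq_len(m)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p >= p[i]
    q[i] <- min(1, min(m / rk[cand] * p[cand]))
  }
  q
}

# All permutations of 1..n (tiny n only), for exact-permutation checks.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Exact two-sided permutation p-value by full enumeration in R.
perm_pvalue_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(spearman_oracle(x, y))
  P <- all_perms(length(y))
  stat <- apply(P, 1, function(pm) abs(stats::cor(rx, ry[pm])))
  mean(stat >= obs - 1e-9)
}

# Small random aligned table with zeros and ties, deterministic per seed.
random_table <- function(seed, np = 30L, ns = 12L) {
  set.seed(seed)
  h <- matrix(round(10^runif(np * ns, 1, 5)), np, ns)
  h[runif(np * ns) < 0.25] <- 0
  aligned_peak_table(sprintf("p%03d", seq_len(np)),
                     mz = runif(np, 100, 1000), rt = runif(np, 0.5, 10),
                     heights = h, fill_fraction = round(runif(np), 3),
                     sample_ids = sprintf("s%02d", seq_len(ns)))
}

# Minimal single-file peak list from parallel vectors.
make_peaklist <- function(heights, sn = rep(10, length(heights)),
                          file_id = "file_a") {
  n <- length(heights)
  file_peak_list(file_id, data.frame(
    mz = seq(100, 100 + n - 1), rt = seq_len(n) / 10,
    height = heights, area = heights * 2, sn = sn))
}

# A one-peak table placing `values` across n samples (zeros elsewhere).
one_peak_table <- function(values, n = 499L, fill = NULL) {
  h <- matrix(0, 1, n)
  h[1, seq_along(values)] <- values
  if (is.null(fill)) fill <- mean(h > 0)
  aligned_peak_table("pk", 500, 5, h, fill, sprintf("s%03d", seq_len(n)))
}
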