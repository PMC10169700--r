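# Independent oracles: naive implementations kept deliberately separate
# from the package's computation paths.

# Spearman rho via the definition: Pearson correlation of average ranks,
# computed with explicit sums (no stats::cor).
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Upper-tail hypergeometric probability by direct summation of the pmf.
enum_hyper_tail <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Exhaustive enumeration of the motif score distribution: every one of the
# 4^w words is scored with real-valued log-odds, giving exact tail
# probabilities under the background.
enum_motif_scores <- function(motif, background = rep(0.25, 4),
                              pseudocount = 0.1) {
  p <- sweep(motif$matrix, 2, background, function(pr, bg)
    (pr + pseudocount * bg) / (1 + pseudocount))
  lo <- log2(sweep(p, 2, background, "/"))
  w <- nrow(lo)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(words))
  probs <- rep(1, nrow(words))
  for (j in seq_len(w)) {
    scores <- scores + lo[j, words[, j]]
    probs <- probs * background[words[, j]]
  }
  list(scores = scores, probs = probs)
}

enum_motif_tail <- function(enum, s) sum(enum$probs[enum$scores >= s])

# Benjamini-Hochberg step-up by the textbook formula, with explicit
# monotonicity enforcement from the largest p downwards.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# A count matrix whose size factors are exactly 1: a majority of
# all-positive genes are constant across samples, so the median ratio is 1
# and normalized counts equal raw counts.
sf1_count_matrix <- function(extra_rows, n_samples,
                             conditions = NULL) {
  n_const <- 2L * nrow(extra_rows) + 10L
  const <- matrix(rep(50L, n_const * n_samples), nrow = n_const,
                  dimnames = list(sprintf("const%04d", seq_len(n_const)),
                                  colnames(extra_rows)))
  counts <- rbind(extra_rows, const)
  if (is.null(conditions))
    conditions <- setNames(rep(c("C", "F"), length.out = n_samples),
                           colnames(extra_rows))
  count_matrix(counts, conditions)
}
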