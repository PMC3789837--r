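# Independent enumeration oracles, kept deliberately brute-force and
# separate from the implementation paths they check.

# upper/lower hypergeometric tail by direct summation of binomial products
hyper_tail_enum <- function(k, n, K, N, tail) {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  support <- lo:hi
  probs <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  if (tail == "over") sum(probs[support >= k]) else sum(probs[support <= k])
}

# two-sided Fisher p by enumerating every table with the observed margins
# and summing the probabilities not exceeding the observed one
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# step-up BH by its defining formula: q_(i) = min_{j >= i} m p_(j) / j
bh_manual <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# brute-force RBBH degree: walk every edge
degree_enum <- function(rbbh, gene, subset) {
  deg <- 0
  for (i in seq_len(nrow(rbbh))) {
    if (rbbh$gene_a[i] == gene && rbbh$gene_b[i] %in% subset) deg <- deg + 1
    if (rbbh$gene_b[i] == gene && rbbh$gene_a[i] %in% subset) deg <- deg + 1
  }
  deg
}
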