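# Independent brute-force oracles, written from the defining formulas and
# kept free of any package internals.

# BH step-up by direct definition: q_(i) = min_{j >= i} n * p_(j) / j.
bh_oracle <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(n * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# AUC by exhaustive pair counting (ties = 1/2).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Within-cell descending order with alphabetical gene-id tiebreak.
rank_desc_oracle <- function(x, genes) {
  o <- order(-x, genes)
  r <- integer(length(x))
  r[o] <- seq_along(x)
  names(r) <- genes
  r
}

# AUCell-type recovery area by explicit step-curve enumeration.
aucell_oracle <- function(x, genes, set, top) {
  r <- rank_desc_oracle(x, genes)
  counts <- vapply(seq_len(top), function(k) sum(r[set] <= k), numeric(1))
  max_counts <- pmin(seq_len(top), length(set))
  sum(counts) / sum(max_counts)
}

# UCell-type score from an explicitly counted Mann-Whitney U between the
# clipped set ranks and the clipped complement ranks.
ucell_oracle <- function(x, genes, set, max_rank) {
  r <- pmin(rank_desc_oracle(x, genes), max_rank)
  rs <- r[set]
  ns <- length(set)
  u <- sum(rs) - ns * (ns + 1) / 2
  1 - u / (ns * (max_rank - ns))
}

# singscore-type score from the defining mean normalized ascending rank.
singscore_oracle <- function(x, genes, set) {
  G <- length(x)
  r_asc <- G - rank_desc_oracle(x, genes) + 1
  mean((r_asc[set] - 0.5) / G) - 0.5
}

# ssGSEA-type integrated running sum by walking the ranked list position by
# position and accumulating the running sum.
ssgsea_oracle <- function(x, genes, set, alpha) {
  r <- rank_desc_oracle(x, genes)
  ord <- names(sort(r))  # genes by descending expression
  G <- length(genes)
  ns <- length(set)
  w <- (G - r + 1)^alpha
  wsum <- sum(w[set])
  running <- 0
  total <- 0
  for (g in ord) {
    if (g %in% set) running <- running + w[[g]] / wsum
    else running <- running - 1 / (G - ns)
    total <- total + running
  }
  total
}
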