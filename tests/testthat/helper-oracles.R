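# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# plug-in mutual information, direct double sum over cells, normalized by
# the column (phenotype) entropy
mi_oracle <- function(counts) {
  p <- counts / sum(counts)
  rp <- rowSums(p)
  cp <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (rp[i] * cp[j]))
    }
  }
  h_p <- -sum(cp[cp > 0] * log2(cp[cp > 0]))
  s / h_p
}

# hypergeometric upper tail by exhaustive enumeration of all draws of k
# from N with items 1..n marked
hyper_oracle <- function(x, N, n, k) {
  if (k == 0) return(as.numeric(x == 0))
  draws <- combn(N, k)
  overlap <- colSums(draws <= n)
  mean(overlap >= x)
}

# Benjamini-Hochberg step-up, direct min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, adj_sorted)[order(o)]
}

# two-sample Welch t statistic (absolute value)
welch_t_abs <- function(x, y) {
  abs((mean(x) - mean(y)) /
        sqrt(var(x) / length(x) + var(y) / length(y)))
}

# dataset of pure background noise
null_dataset <- function(n_genes, seed, n_toxic = 30, n_nontoxic = 30) {
  simulate_dataset(sim_config(n_genes = n_genes, n_toxic = n_toxic,
                              n_nontoxic = n_nontoxic, seed = seed))
}

planted_gene_ids <- function(dataset) {
  split(dataset$genes$gene_id[dataset$genes$role == "pair"],
        dataset$genes$pair_id[dataset$genes$role == "pair"])
}

# edges of a network as a sorted "a|b" key vector
edge_keys <- function(network) {
  e <- network$edges
  sort(paste(pmin(e$gene1, e$gene2), pmax(e$gene1, e$gene2), sep = "|"))
}

pair_key <- function(g) paste(sort(g), collapse = "|")
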