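#' Hypergeometric upper-tail probability
#'
#' Probability of observing `x` or more pathway genes among a gene's network
#' neighbors (equivalently, in a random draw of `k` genes from `N` with `n`
#' marked):
#' `p = sum_{i = x}^{min(n, k)} choose(n, i) * choose(N - n, k - i) / choose(N, k)`.
#' Evaluated through [stats::phyper()] (log-space-stable). Vectorized with
#' recycling.
#'
#' @param x Observed overlap (`0 <= x <= min(n, k)`).
#' @param N Universe size (genes in the network for neighbor association;
#'   background genes for pathway enrichment).
#' @param n Number of marked genes (pathway genes) in the universe.
#' @param k Draw size (a gene's degree, or the network gene count).
#' @return Upper-tail probability in (0, 1].
#' @examples
#' hypergeom_tail(0, 10, 3, 4)    # 1
#' hypergeom_tail(2, 4, 2, 2)     # 1/6
#' @export
hypergeom_tail <- function(x, N, n, k) {
  len <- max(length(x), length(N), length(n), length(k))
  x <- rep_len(x, len); N <- rep_len(N, len)
  n <- rep_len(n, len); k <- rep_len(k, len)
  ok <- x >= 0 & n >= 0 & k >= 0 & n <= N & k <= N & x <= pmin(n, k)
  if (any(!ok)) {
    i <- which(!ok)[1]
    abort(sprintf("invalid hypergeometric parameters: x=%g N=%g n=%g k=%g",
                  x[i], N[i], n[i], k[i]))
  }
  phyper(x - 1, n, N - n, k, lower.tail = FALSE)
}

#' Pathway over-representation in a gene network
#'
#' One-sided hypergeometric test per pathway for enrichment among the
#' network genes relative to a background universe, with Benjamini-Hochberg
#' adjustment across pathways. The background defaults naturally to the
#' selected-gene universe that entered the synergy analysis (pass the full
#' pre-selection universe to widen it).
#'
#' @param network_genes Character vector of genes in the network (must be a
#'   subset of `background`), or a `gene_network`.
#' @param background Character vector: the gene universe.
#' @param gene_sets Named list of pathways (e.g. from [read_gmt()]). Sets
#'   with no member in the background are dropped with a message.
#' @param alpha Adjusted-p cutoff for the `significant` flag (default 0.05).
#' @return A tibble sorted by p-value: `pathway`, `n_background` (pathway
#'   genes in the universe), `n_network` (pathway genes in the network),
#'   `p`, `p_adj`, `significant`.
#' @export
enrich_pathways <- function(network_genes, background, gene_sets,
                            alpha = 0.05) {
  if (inherits(network_genes, "gene_network")) {
    network_genes <- network_genes(network_genes)
  }
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  outside <- setdiff(network_genes, background)
  if (length(outside)) {
    abort(paste0("network gene absent from background: ", outside[1]))
  }
  members <- lapply(gene_sets, intersect, background)
  empty <- lengths(members) == 0
  if (any(empty)) {
    message(sum(empty), " gene set(s) with no background member dropped: ",
            paste(names(members)[empty], collapse = ", "))
    members <- members[!empty]
  }
  if (length(members) == 0) {
    return(tibble(pathway = character(), n_background = integer(),
                  n_network = integer(), p = numeric(), p_adj = numeric(),
                  significant = logical()))
  }
  N <- length(unique(background))
  k <- length(unique(network_genes))
  n <- lengths(members)
  x <- vapply(members, function(m) length(intersect(m, network_genes)), 0L)
  p <- hypergeom_tail(x, N, n, k)
  tibble(pathway = names(members),
         n_background = unname(n), n_network = unname(x),
         p = unname(p), p_adj = bh_adjust(unname(p))) |>
    mutate(significant = .data$p_adj < alpha) |>
    arrange(.data$p, .data$pathway)
}

#' Pathway-neighbor association in a gene network
#'
#' Ranks the non-pathway network genes connected to at least
#' `min_connections` pathway genes by the hypergeometric tail probability of
#' their pathway adjacency: with `N` genes in the network, `n` pathway genes
#' in the network, a neighbor of degree `k` connected to `x` pathway genes
#' scores `hypergeom_tail(x, N, n, k)`. P-values are adjusted by
#' Benjamini-Hochberg across the tested neighbors of this pathway.
#'
#' @param network A `gene_network`.
#' @param pathway_genes Character vector of pathway member gene ids; members
#'   absent from the network are dropped with a message.
#' @param min_connections Minimum pathway adjacency for a neighbor to be
#'   tested (default 3).
#' @param alpha Adjusted-p cutoff for the `significant` flag.
#' @return A tibble ranked by `p_adj`, then `p`, then gene id: `gene`, `x`,
#'   `N`, `n`, `k`, `p`, `p_adj`, `rank`, `significant`.
#' @export
associate_neighbors <- function(network, pathway_genes, min_connections = 3,
                                alpha = 0.05) {
  stopifnot(inherits(network, "gene_network"))
  nodes <- network_genes(network)
  if (length(nodes) == 0 || igraph::ecount(network$graph) == 0) {
    abort("empty network")
  }
  present <- intersect(pathway_genes, nodes)
  absent <- setdiff(pathway_genes, nodes)
  if (length(absent)) {
    message(length(absent), " pathway gene(s) not in the network dropped: ",
            paste(absent, collapse = ", "))
  }
  N <- length(nodes)
  n <- length(present)
  candidates <- setdiff(nodes, present)
  adj <- igraph::adjacent_vertices(network$graph, candidates)
  x <- vapply(adj, function(v) {
    length(intersect(igraph::as_ids(v), present))
  }, 0L)
  k <- igraph::degree(network$graph)[candidates]
  tested <- x >= min_connections
  if (!any(tested)) {
    return(tibble(gene = character(), x = integer(), N = integer(),
                  n = integer(), k = integer(), p = numeric(),
                  p_adj = numeric(), rank = integer(),
                  significant = logical()))
  }
  out <- tibble(gene = candidates[tested],
                x = as.integer(x[tested]), N = N, n = n,
                k = as.integer(k[tested]))
  out |>
    mutate(p = hypergeom_tail(.data$x, .data$N, .data$n, .data$k),
           p_adj = bh_adjust(.data$p)) |>
    arrange(.data$p_adj, .data$p, .data$gene) |>
    mutate(rank = min_rank(.data$p), significant = .data$p_adj < alpha)
}
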