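# internal constructor: gene_network from an igraph (and optional edge data)
new_gene_network <- function(graph, edges = NULL, alpha = NA_real_,
                             type = "synergy") {
  if (is.null(edges)) {
    el <- igraph::as_edgelist(graph)
    edges <- tibble(gene1 = el[, 1], gene2 = el[, 2])
  }
  structure(list(graph = graph, edges = as_tibble(edges), alpha = alpha,
                 type = type),
            class = "gene_network")
}

#' Assemble the gene-cooperation network from a synergy scan
#'
#' Edges are the gene pairs with positive synergy and Benjamini-Hochberg
#' adjusted p-value below `alpha`; nodes are the genes incident to at least
#' one edge (isolated genes are excluded).
#'
#' @param results A `synergy_scan` or its per-pair tibble (must contain
#'   `gene1`, `gene2`, `syn`, `p_adj`; each unordered pair at most once).
#' @param alpha Adjusted-p cutoff (default: the scan's `alpha`, else 0.05).
#' @return A `gene_network`: list with the `igraph` graph, the `edges`
#'   tibble (`gene1`, `gene2`, `syn`, `p_adj`, `pattern` if available), the
#'   cutoff and the network type.
#' @export
build_network <- function(results, alpha = NULL) {
  if (inherits(results, "synergy_scan")) {
    if (is.null(alpha)) alpha <- results$alpha
    results <- results$pairs
  }
  if (is.null(alpha)) alpha <- 0.05
  results <- as_tibble(results)
  req <- c("gene1", "gene2", "syn", "p_adj")
  if (!all(req %in% names(results))) {
    abort(paste0("results must have columns: ", paste(req, collapse = ", ")))
  }
  key <- paste(pmin(results$gene1, results$gene2),
               pmax(results$gene1, results$gene2))
  if (anyDuplicated(key)) {
    abort(paste0("duplicate gene pair: ", key[duplicated(key)][1]))
  }
  edges <- results |> filter(.data$syn > 0, .data$p_adj < alpha)
  keep <- intersect(c("gene1", "gene2", "syn", "p_adj", "pattern"),
                    names(edges))
  edges <- edges[, keep]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  new_gene_network(g, edges, alpha = alpha, type = "synergy")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network:%s> %d genes, %d edges\n", x$type,
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Genes in a network
#' @param network A `gene_network`.
#' @return Character vector of node gene ids.
#' @export
network_genes <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  igraph::V(network$graph)$name
}

#' Node degrees of a network
#' @param network A `gene_network`.
#' @return Named integer vector of degrees.
#' @export
network_degrees <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  igraph::degree(network$graph)
}

#' Compare network topology against an Erdos-Renyi random graph
#'
#' Generates one Erdos-Renyi `G(n, m)` graph with the same node and edge
#' counts as the network and contrasts the two degree sequences: degree
#' histograms plus the two-sample Kolmogorov-Smirnov statistic. A hub-heavy
#' (power-law-like) cooperation network departs visibly from the bell-shaped
#' random-graph degree distribution.
#'
#' @param network A `gene_network` with at least one edge.
#' @param seed Seed for the random graph.
#' @return A `topology_report`: list with `degrees` (tibble `graph`,
#'   `gene`, `degree`), `histogram` (tibble `graph`, `degree`, `n`) and
#'   `ks_statistic`.
#' @export
topology_report <- function(network, seed = 1) {
  stopifnot(inherits(network, "gene_network"))
  n <- igraph::vcount(network$graph)
  m <- igraph::ecount(network$graph)
  if (m < 1) abort("empty network")
  er <- with_substream(seed, igraph::sample_gnm(n, m))
  d_net <- igraph::degree(network$graph)
  d_er <- igraph::degree(er)
  degrees <- bind_rows(
    tibble(graph = "network", gene = names(d_net), degree = as.integer(d_net)),
    tibble(graph = "random", gene = NA_character_, degree = as.integer(d_er)))
  histogram <- degrees |> count(.data$graph, .data$degree)
  ks <- suppressWarnings(ks.test(d_net, d_er))$statistic
  structure(list(degrees = degrees, histogram = histogram,
                 ks_statistic = unname(ks)),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> KS(degree_net, degree_random) = %.4f\n",
              x$ks_statistic))
  invisible(x)
}
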