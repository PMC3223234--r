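#' Tidy a synergy scan
#' @param x A `synergy_scan`.
#' @param ... Unused.
#' @return The per-pair tibble.
#' @exportS3Method generics::tidy
tidy.synergy_scan <- function(x, ...) x$pairs

#' One-row summary of a synergy scan
#' @param x A `synergy_scan`.
#' @param ... Unused.
#' @return A one-row tibble: pair counts, significant counts, settings.
#' @exportS3Method generics::glance
glance.synergy_scan <- function(x, ...) {
  tibble(n_genes = length(x$genes), n_pairs = nrow(x$pairs),
         n_positive = sum(x$pairs$syn > 0),
         n_significant = sum(x$pairs$p_adj < x$alpha & x$pairs$syn > 0),
         B = x$B, alpha = x$alpha, method = x$method,
         n_states = x$n_states)
}

#' Tidy a gene network
#' @param x A `gene_network`.
#' @param ... Unused.
#' @return The edges tibble.
#' @exportS3Method generics::tidy
tidy.gene_network <- function(x, ...) x$edges

#' One-row summary of a gene network
#' @param x A `gene_network`.
#' @param ... Unused.
#' @return A one-row tibble: node/edge counts, density, max degree, type.
#' @exportS3Method generics::glance
glance.gene_network <- function(x, ...) {
  tibble(n_genes = igraph::vcount(x$graph),
         n_edges = igraph::ecount(x$graph),
         density = igraph::edge_density(x$graph),
         max_degree = if (igraph::vcount(x$graph)) {
           max(igraph::degree(x$graph))
         } else 0L,
         alpha = x$alpha, type = x$type)
}

#' Tidy a differential-correlation scan
#' @param x A `diffcorr_scan`.
#' @param ... Unused.
#' @return The per-pair tibble.
#' @exportS3Method generics::tidy
tidy.diffcorr_scan <- function(x, ...) x$pairs

#' One-row summary of a differential-correlation scan
#' @param x A `diffcorr_scan`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.diffcorr_scan <- function(x, ...) {
  tibble(n_genes = length(x$genes), n_pairs = nrow(x$pairs),
         n_significant = sum(x$pairs$p_adj < x$alpha),
         alpha = x$alpha, method = x$method)
}

#' Tidy a topology report
#' @param x A `topology_report`.
#' @param ... Unused.
#' @return The per-node degree tibble.
#' @exportS3Method generics::tidy
tidy.topology_report <- function(x, ...) x$degrees

#' One-row summary of a topology report
#' @param x A `topology_report`.
#' @param ... Unused.
#' @return A one-row tibble with the KS statistic.
#' @exportS3Method generics::glance
glance.topology_report <- function(x, ...) {
  tibble(ks_statistic = x$ks_statistic)
}
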