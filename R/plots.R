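#' Joint-expression plot of a gene pair
#'
#' Scatter of the two genes' expression with samples colored by phenotype:
#' the standard way of looking at a cooperative pair (a gap pair shows the
#' two phenotypes separated along the diagonal difference axis while both
#' marginals overlap).
#'
#' @param dataset An `expr_dataset`.
#' @param gene1,gene2 Gene ids.
#' @return A ggplot.
#' @export
plot_pair <- function(dataset, gene1, gene2) {
  stopifnot(inherits(dataset, "expr_dataset"))
  miss <- setdiff(c(gene1, gene2), rownames(dataset$values))
  if (length(miss)) abort(paste0("unknown gene: ", miss[1]))
  df <- tibble(g1 = dataset$values[gene1, ],
               g2 = dataset$values[gene2, ],
               phenotype = dataset$samples$phenotype)
  ggplot(df, aes(x = .data$g1, y = .data$g2, color = .data$phenotype)) +
    geom_point(alpha = 0.8) +
    labs(x = gene1, y = gene2, color = "phenotype") +
    theme_minimal()
}

#' Synergy-versus-significance plot of a scan
#'
#' @param object A `synergy_scan`.
#' @param ... Unused.
#' @return A ggplot: synergy score against `-log10` raw p, colored by
#'   BH significance.
#' @exportS3Method ggplot2::autoplot
autoplot.synergy_scan <- function(object, ...) {
  df <- object$pairs |>
    mutate(significant = .data$p_adj < object$alpha & .data$syn > 0)
  ggplot(df, aes(x = .data$syn, y = -log10(.data$p_raw),
                 color = .data$significant)) +
    geom_point(alpha = 0.6) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "information synergy", y = expression(-log[10] ~ p),
         color = "edge") +
    theme_minimal()
}

#' Degree-distribution plot of a network
#'
#' @param object A `gene_network`.
#' @param ... Unused.
#' @return A ggplot of the degree histogram.
#' @exportS3Method ggplot2::autoplot
autoplot.gene_network <- function(object, ...) {
  df <- tibble(degree = as.integer(network_degrees(object)))
  ggplot(df, aes(x = .data$degree)) +
    geom_bar() +
    labs(x = "degree", y = "genes") +
    theme_minimal()
}

#' Degree-distribution comparison plot
#'
#' @param object A `topology_report`.
#' @param ... Unused.
#' @return A ggplot contrasting the network and random-graph degree
#'   histograms.
#' @exportS3Method ggplot2::autoplot
autoplot.topology_report <- function(object, ...) {
  ggplot(object$histogram,
         aes(x = .data$degree, y = .data$n, fill = .data$graph)) +
    geom_col(position = "dodge") +
    labs(x = "degree", y = "genes", fill = NULL) +
    theme_minimal()
}
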