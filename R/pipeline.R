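#' Run the full synergy-analysis pipeline
#'
#' Orchestrates every stage on one dataset: trend-based gene selection,
#' pairwise synergy scan with permutation testing, network assembly,
#' topology diagnostics, pathway enrichment, pathway-neighbor association
#' for each significant pathway, and the differential-correlation baseline.
#' With `out_dir` set, every stage report is written as a TSV (plus a
#' SIF-style edge list and a JSON run manifest); a fixed seed makes the run,
#' and the written files, fully reproducible.
#'
#' @param dataset An `expr_dataset`.
#' @param gene_sets Optional named list of pathways (e.g. [read_gmt()]);
#'   defaults to the simulator's planted sets when present. Without gene
#'   sets the enrichment and association stages are skipped.
#' @param out_dir Optional output directory.
#' @param select_alpha Gene-selection t-test cutoff (default 0.05).
#' @param trend_tol Trend-matching tolerance (default 0).
#' @param B Permutations for the synergy test (default 1000).
#' @param edge_alpha Adjusted-p cutoff for network edges (default 0.05).
#' @param assoc_alpha Adjusted-p cutoff for enrichment/association
#'   (default 0.05).
#' @param min_connections Neighbor-association connection threshold
#'   (default 3).
#' @param n_states,method Mutual-information estimator settings
#'   (see [discretize_2d()]).
#' @param background Enrichment universe: `"selected"` (the genes entering
#'   the synergy analysis; default) or `"all"` (every gene in the dataset).
#' @param run_diffcorr Run the differential-correlation baseline
#'   (default TRUE).
#' @param seed Root seed; stochastic stages derive fixed offsets from it.
#' @return A `synergy_pipeline` object: list with `selection`, `scan`,
#'   `network`, `topology`, `enrichment`, `associations`, `diffcorr`,
#'   `diffcorr_network`, `config`, and `paths` when files were written.
#' @export
run_pipeline <- function(dataset, gene_sets = attr(dataset, "gene_sets"),
                         out_dir = NULL,
                         select_alpha = 0.05, trend_tol = 0, B = 1000,
                         edge_alpha = 0.05, assoc_alpha = 0.05,
                         min_connections = 3, n_states = 3,
                         method = c("grid", "cluster"),
                         background = c("selected", "all"),
                         run_diffcorr = TRUE, seed = 1) {
  method <- match.arg(method)
  background <- match.arg(background)
  stopifnot(inherits(dataset, "expr_dataset"))
  seed <- as.integer(seed)
  config <- list(select_alpha = select_alpha, trend_tol = trend_tol, B = B,
                 edge_alpha = edge_alpha, assoc_alpha = assoc_alpha,
                 min_connections = min_connections, n_states = n_states,
                 method = method, background = background, seed = seed)

  selection <- select_genes(dataset, alpha = select_alpha, tol = trend_tol)
  kept <- selection$gene[selection$kept]
  if (length(kept) < 2) {
    abort(sprintf("stage gene_selection: only %d gene(s) kept, need >= 2",
                  length(kept)))
  }
  scan <- synergy_scan(dataset, genes = kept, B = B, alpha = edge_alpha,
                       n_states = n_states, method = method, seed = seed + 1L)
  network <- build_network(scan, alpha = edge_alpha)
  topology <- if (igraph::ecount(network$graph) > 0) {
    topology_report(network, seed = seed + 2L)
  } else NULL

  enrichment <- NULL
  associations <- NULL
  if (!is.null(gene_sets) && igraph::vcount(network$graph) > 0) {
    bg <- if (background == "selected") kept else rownames(dataset$values)
    enrichment <- enrich_pathways(network_genes(network), bg, gene_sets,
                                  alpha = assoc_alpha)
    sig <- enrichment$pathway[enrichment$significant]
    associations <- purrr::map_dfr(sig, function(pw) {
      res <- associate_neighbors(network, gene_sets[[pw]],
                                 min_connections = min_connections,
                                 alpha = assoc_alpha)
      if (nrow(res)) mutate(res, pathway = pw, .before = 1) else NULL
    })
    if (is.null(associations) || nrow(associations) == 0) {
      associations <- tibble(pathway = character(), gene = character(),
                             x = integer(), N = integer(), n = integer(),
                             k = integer(), p = numeric(), p_adj = numeric(),
                             rank = integer(), significant = logical())
    }
  }

  diffcorr <- NULL
  diffcorr_network <- NULL
  if (run_diffcorr) {
    diffcorr <- diffcorr_scan(dataset, genes = kept, alpha = edge_alpha)
    diffcorr_network <- build_diffcorr_network(diffcorr)
  }

  res <- structure(list(selection = selection, scan = scan,
                        network = network, topology = topology,
                        enrichment = enrichment, associations = associations,
                        diffcorr = diffcorr,
                        diffcorr_network = diffcorr_network,
                        config = config),
                   class = "synergy_pipeline")
  if (!is.null(out_dir)) {
    res$paths <- write_pipeline(res, out_dir)
  }
  res
}

# write all stage reports of a pipeline run; returns named paths
write_pipeline <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  paths <- c(selection = p("selection.tsv"),
             synergy_pairs = p("synergy_pairs.tsv"),
             network_edges = p("network_edges.tsv"),
             network_sif = p("network.sif"),
             manifest = p("manifest.json"))
  readr::write_tsv(res$selection, paths[["selection"]])
  readr::write_tsv(res$scan$pairs, paths[["synergy_pairs"]])
  readr::write_tsv(res$network$edges, paths[["network_edges"]])
  write_sif(res$network, paths[["network_sif"]])
  if (!is.null(res$topology)) {
    paths[["topology"]] <- p("topology.tsv")
    readr::write_tsv(res$topology$histogram, paths[["topology"]])
  }
  if (!is.null(res$enrichment)) {
    paths[["enrichment"]] <- p("enrichment.tsv")
    readr::write_tsv(res$enrichment, paths[["enrichment"]])
  }
  if (!is.null(res$associations)) {
    paths[["associations"]] <- p("associations.tsv")
    readr::write_tsv(res$associations, paths[["associations"]])
  }
  if (!is.null(res$diffcorr)) {
    paths[["diffcorr_pairs"]] <- p("diffcorr_pairs.tsv")
    paths[["diffcorr_edges"]] <- p("diffcorr_edges.tsv")
    readr::write_tsv(res$diffcorr$pairs, paths[["diffcorr_pairs"]])
    readr::write_tsv(res$diffcorr_network$edges, paths[["diffcorr_edges"]])
  }
  manifest <- c(res$config,
                list(package_version = as.character(packageVersion("synergynet")),
                     n_genes_total = nrow(res$selection),
                     n_genes_selected = sum(res$selection$kept),
                     n_pairs_tested = nrow(res$scan$pairs),
                     n_network_genes = igraph::vcount(res$network$graph),
                     n_network_edges = igraph::ecount(res$network$graph),
                     n_pathways_significant =
                       if (is.null(res$enrichment)) 0L
                       else sum(res$enrichment$significant),
                     n_diffcorr_edges =
                       if (is.null(res$diffcorr_network)) NA_integer_
                       else igraph::ecount(res$diffcorr_network$graph)))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths
}

#' @export
print.synergy_pipeline <- function(x, ...) {
  cat("<synergy_pipeline>\n")
  cat(sprintf("  selected genes : %d / %d\n",
              sum(x$selection$kept), nrow(x$selection)))
  cat(sprintf("  pairs tested   : %d (B = %d)\n",
              nrow(x$scan$pairs), x$scan$B))
  cat(sprintf("  synergy network: %d genes, %d edges\n",
              igraph::vcount(x$network$graph), igraph::ecount(x$network$graph)))
  if (!is.null(x$enrichment)) {
    cat(sprintf("  pathways       : %d significant / %d tested\n",
                sum(x$enrichment$significant), nrow(x$enrichment)))
  }
  if (!is.null(x$associations) && nrow(x$associations)) {
    top <- x$associations |> arrange(.data$p_adj, .data$p) |> slice(1)
    cat(sprintf("  top neighbor   : %s (pathway %s, p_adj = %.3g)\n",
                top$gene, top$pathway, top$p_adj))
  }
  if (!is.null(x$diffcorr_network)) {
    cat(sprintf("  diffcorr net   : %d genes, %d edges\n",
                igraph::vcount(x$diffcorr_network$graph),
                igraph::ecount(x$diffcorr_network$graph)))
  }
  invisible(x)
}
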