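#' Differential-correlation test for one gene pair
#'
#' The baseline comparison method: within each phenotype class the pair's
#' correlation coefficient is computed, Fisher z-transformed, and the two
#' transforms compared with
#' `z = (z_toxic - z_nontoxic) / sqrt(1/(n1 - 3) + 1/(n2 - 3))`,
#' giving a two-sided normal p-value for a difference in coexpression
#' between phenotypes.
#'
#' @param g1,g2 Expression vectors.
#' @param phenotype Two-class labels (at least 4 samples per class).
#' @param method Correlation type: `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `r_toxic`, `r_nontoxic`, `z`, `p`.
#' @export
diffcorr_test <- function(g1, g2, phenotype,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(g1) == length(g2))
  ph <- check_phenotype(phenotype, length(g1))
  pos <- ph == positive_class(ph)
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 <= 3 || n2 <= 3) {
    abort("each phenotype class needs more than 3 samples")
  }
  if (sd(g1[pos]) == 0 || sd(g2[pos]) == 0 ||
      sd(g1[!pos]) == 0 || sd(g2[!pos]) == 0) {
    abort("zero-variance gene within a phenotype class")
  }
  r1 <- cor(g1[pos], g2[pos], method = method)
  r2 <- cor(g1[!pos], g2[!pos], method = method)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(r_toxic = r1, r_nontoxic = r2, z = z,
         p = 2 * pnorm(-abs(z)))
}

#' Differential-correlation scan over all gene pairs
#'
#' Applies [diffcorr_test()] to every unordered gene pair (vectorized
#' through per-class correlation matrices) and adjusts the p-values across
#' pairs by Benjamini-Hochberg.
#'
#' @param dataset An `expr_dataset`.
#' @param genes Optional gene subset.
#' @param alpha Adjusted-p cutoff stored for [build_diffcorr_network()].
#' @param method Correlation type.
#' @return A `diffcorr_scan` object; `tidy()` returns the per-pair tibble
#'   (`gene1`, `gene2`, `r_toxic`, `r_nontoxic`, `z`, `p`, `p_adj`).
#' @export
diffcorr_scan <- function(dataset, genes = NULL, alpha = 0.05,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "expr_dataset"))
  if (is.null(genes)) genes <- rownames(dataset$values)
  X <- dataset$values[genes, , drop = FALSE]
  ph <- check_phenotype(dataset$samples$phenotype, ncol(X))
  pos <- ph == positive_class(ph)
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 <= 3 || n2 <= 3) {
    abort("each phenotype class needs more than 3 samples")
  }
  const1 <- apply(X[, pos, drop = FALSE], 1, sd) == 0
  const2 <- apply(X[, !pos, drop = FALSE], 1, sd) == 0
  if (any(const1 | const2)) {
    abort(paste0("zero-variance gene within a phenotype class: ",
                 genes[const1 | const2][1]))
  }
  R1 <- cor(t(X[, pos, drop = FALSE]), method = method)
  R2 <- cor(t(X[, !pos, drop = FALSE]), method = method)
  pairs <- gene_pairs(genes)
  ii <- match(pairs$gene1, genes)
  jj <- match(pairs$gene2, genes)
  idx <- cbind(ii, jj)
  r1 <- R1[idx]; r2 <- R2[idx]
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  res <- pairs |>
    mutate(r_toxic = r1, r_nontoxic = r2, z = z,
           p = pmin(pmax(2 * pnorm(-abs(z)), .Machine$double.xmin), 1))
  res$p_adj <- bh_adjust(res$p)
  structure(list(pairs = res, genes = genes, alpha = alpha, method = method),
            class = "diffcorr_scan")
}

#' @export
print.diffcorr_scan <- function(x, ...) {
  cat(sprintf("<diffcorr_scan> %d genes, %d pairs; BH-significant at %.3g: %d\n",
              length(x$genes), nrow(x$pairs), x$alpha,
              sum(x$pairs$p_adj < x$alpha)))
  invisible(x)
}

#' Assemble the differential-correlation network
#'
#' Edges are the gene pairs whose within-phenotype correlations differ
#' significantly after Benjamini-Hochberg adjustment.
#'
#' @param scan A `diffcorr_scan` (or an `expr_dataset`, which is scanned
#'   first with default settings).
#' @param alpha Adjusted-p cutoff (default: the scan's `alpha`).
#' @return A `gene_network` of type `"diffcorr"`.
#' @export
build_diffcorr_network <- function(scan, alpha = NULL) {
  if (inherits(scan, "expr_dataset")) scan <- diffcorr_scan(scan)
  stopifnot(inherits(scan, "diffcorr_scan"))
  if (is.null(alpha)) alpha <- scan$alpha
  edges <- scan$pairs |> filter(.data$p_adj < alpha)
  edges <- edges[, c("gene1", "gene2", "z", "p_adj")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  new_gene_network(g, edges, alpha = alpha, type = "diffcorr")
}
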