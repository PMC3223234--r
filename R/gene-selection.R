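#' Preprocess raw expression data
#'
#' Optional log2 transformation, probe-to-gene averaging, and removal of
#' unannotated genes. Mirrors the usual microarray preprocessing ahead of
#' trend-based gene selection: expression is log2 scale, multiple probes of
#' one gene are averaged, and genes without functional annotation (e.g.
#' ESTs / hypothetical proteins) can be dropped via a caller-supplied
#' blacklist.
#'
#' @param dataset An `expr_dataset` (rows may be probes).
#' @param probe_map Optional probe-to-gene map: a data frame with columns
#'   `probe_id`, `gene_id` (or a named character vector probe -> gene).
#'   Probe rows mapping to the same gene are averaged (on the log2 scale,
#'   after any transformation). Probes absent from the map are dropped.
#' @param log2_transform If `TRUE`, apply `log2()` first; all values must be
#'   strictly positive.
#' @param drop_genes Optional character vector of gene ids to remove after
#'   averaging (annotation blacklist).
#' @return A preprocessed `expr_dataset` with one row per gene.
#' @examples
#' ds <- simulate_dataset(sim_config(n_genes = 4, n_toxic = 3, n_nontoxic = 3))
#' pm <- data.frame(probe_id = rownames(ds$values),
#'                  gene_id = c("A", "A", "B", "C"))
#' preprocess(ds, probe_map = pm)
#' @export
preprocess <- function(dataset, probe_map = NULL, log2_transform = FALSE,
                       drop_genes = NULL) {
  stopifnot(inherits(dataset, "expr_dataset"))
  values <- dataset$values
  if (log2_transform) {
    if (any(values <= 0)) {
      bad <- which(values <= 0, arr.ind = TRUE)[1, ]
      abort(sprintf("non-positive value at gene %s, sample %s: cannot log2",
                    rownames(values)[bad[1]], colnames(values)[bad[2]]))
    }
    values <- log2(values)
  }
  if (!is.null(probe_map)) {
    if (!is.data.frame(probe_map)) {
      probe_map <- tibble(probe_id = names(probe_map),
                          gene_id = unname(probe_map))
    }
    stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
    probe_map <- probe_map[probe_map$probe_id %in% rownames(values), ]
    grp <- split(probe_map$probe_id, probe_map$gene_id)
    values <- do.call(rbind, lapply(grp, function(p) {
      colMeans(values[p, , drop = FALSE])
    }))
    rownames(values) <- names(grp)
  }
  if (!is.null(drop_genes)) {
    values <- values[!rownames(values) %in% drop_genes, , drop = FALSE]
  }
  expr_dataset(values, dataset$samples)
}

#' Match condition means to a metabolite trend
#'
#' The four representative metabolite trends over the BSA (control),
#' palmitate and oleate conditions, as strict orderings of the per-condition
#' means:
#' \itemize{
#'   \item I: BSA < PA and PA > OA
#'   \item II: BSA > PA and PA < OA
#'   \item III: BSA < PA < OA
#'   \item IV: BSA > PA > OA
#' }
#' The four predicates are mutually exclusive; ties (within `tol`) match
#' nothing.
#'
#' @param m_bsa,m_pa,m_oa Per-condition mean expression (vectorized).
#' @param tol Tolerance band: inequalities must hold by more than `tol`
#'   (default 0, i.e. plain strict inequalities).
#' @return Character vector of trend codes (`"I"`..`"IV"`) or `NA` where no
#'   trend matches.
#' @examples
#' match_trend(1, 2, 3)   # "III"
#' match_trend(1, 3, 2)   # "I"
#' match_trend(2, 2, 3)   # NA: tie
#' @export
match_trend <- function(m_bsa, m_pa, m_oa, tol = 0) {
  stopifnot(tol >= 0)
  up1 <- m_pa - m_bsa > tol    # BSA < PA
  dn1 <- m_bsa - m_pa > tol    # BSA > PA
  up2 <- m_oa - m_pa > tol     # PA < OA
  dn2 <- m_pa - m_oa > tol     # PA > OA
  out <- rep(NA_character_, length(up1))
  out[up1 & up2] <- "III"
  out[dn1 & dn2] <- "IV"
  out[up1 & dn2] <- "I"
  out[dn1 & up2] <- "II"
  out[!is.finite(m_bsa) | !is.finite(m_pa) | !is.finite(m_oa)] <- NA_character_
  out
}

# Welch t-test p-value, safe on degenerate input (constant groups -> p = 1)
welch_p <- function(x, y) {
  tryCatch(t.test(x, y)$p.value, error = function(e) 1)
}

#' Trend- and differential-expression-based gene selection
#'
#' Keeps genes whose per-condition mean expression matches one of the four
#' metabolite trends ([match_trend()]) and that are differentially expressed
#' between at least one pair of conditions by a Welch two-sample t-test at
#' level `alpha`.
#'
#' @param dataset An `expr_dataset` with conditions `BSA`, `PA`, `OA`
#'   (at least 2 samples each).
#' @param alpha Per-test p-value cutoff (default 0.05).
#' @param tol Trend-matching tolerance, passed to [match_trend()].
#' @param drop_genes Optional blacklist applied before selection.
#' @return A tibble (the selection report), one row per gene: `gene`,
#'   `m_BSA`, `m_PA`, `m_OA`, `trend`, `p_BSA_PA`, `p_PA_OA`, `p_BSA_OA`,
#'   `kept`. Selected genes are `dplyr::filter(report, kept)$gene`.
#' @export
select_genes <- function(dataset, alpha = 0.05, tol = 0, drop_genes = NULL) {
  stopifnot(inherits(dataset, "expr_dataset"), alpha >= 0, alpha <= 1)
  values <- dataset$values
  if (!is.null(drop_genes)) {
    values <- values[!rownames(values) %in% drop_genes, , drop = FALSE]
  }
  cond <- dataset$samples$condition
  req <- c("BSA", "PA", "OA")
  counts <- table(factor(cond, levels = req))
  if (any(counts < 2)) {
    abort(sprintf("condition %s has fewer than 2 samples",
                  req[which(counts < 2)[1]]))
  }
  cols <- lapply(req, function(cc) which(cond == cc))
  names(cols) <- req
  m <- vapply(cols, function(j) rowMeans(values[, j, drop = FALSE]),
              numeric(nrow(values)))
  if (nrow(values) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, req))
  trend <- match_trend(m[, "BSA"], m[, "PA"], m[, "OA"], tol = tol)
  pmat <- t(vapply(seq_len(nrow(values)), function(i) {
    x <- values[i, ]
    c(welch_p(x[cols$BSA], x[cols$PA]),
      welch_p(x[cols$PA], x[cols$OA]),
      welch_p(x[cols$BSA], x[cols$OA]))
  }, numeric(3)))
  kept <- !is.na(trend) & (pmat[, 1] < alpha | pmat[, 2] < alpha |
                             pmat[, 3] < alpha)
  tibble(gene = rownames(values),
         m_BSA = m[, "BSA"], m_PA = m[, "PA"], m_OA = m[, "OA"],
         trend = trend,
         p_BSA_PA = pmat[, 1], p_PA_OA = pmat[, 2], p_BSA_OA = pmat[, 3],
         kept = kept)
}
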