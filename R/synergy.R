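#' Normalized mutual information from a contingency table
#'
#' Plug-in (maximum-likelihood) mutual information, in bits, between
#' discretized expression states (rows) and phenotype classes (columns),
#' divided by the phenotype entropy `H(P)`. The normalization puts mutual
#' information on a `[0, 1]` scale (1 = the states determine the phenotype)
#' and gives the synergy score its `[-1, 1]` range for a binary phenotype.
#'
#' @param counts Non-negative count matrix, expression states x phenotype
#'   classes.
#' @return Normalized mutual information in `[0, 1]`.
#' @examples
#' mutual_information(matrix(c(50, 0, 0, 50), 2))     # 1: perfect association
#' mutual_information(matrix(c(25, 25, 25, 25), 2))   # 0: independence
#' @export
mutual_information <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts)) abort("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) abort("table total must be positive")
  h_p <- entropy_bits(colSums(counts))
  if (h_p == 0) abort("degenerate phenotype: column entropy is zero")
  h_s <- entropy_bits(rowSums(counts))
  h_sp <- entropy_bits(counts)
  mi <- h_s + h_p - h_sp
  max(mi, 0) / h_p
}

#' Information synergy of a gene pair with respect to a phenotype
#'
#' The synergy score is the gain in (normalized) mutual information about
#' the phenotype from the pair's joint expression over the sum of the two
#' marginal contributions:
#' `syn = I(G1,G2; P) - I(G1; P) - I(G2; P)`,
#' with every mutual information normalized by the phenotype entropy. With
#' the default grid discretization the score lies in `[-1, 1]` by
#' construction: positive scores mean the genes cooperate in discriminating
#' the phenotype, negative scores mean they carry redundant information.
#'
#' @param g1,g2 Numeric expression vectors (equal length).
#' @param phenotype Two-class label vector, same length.
#' @param n_states Marginal discretization states (default 3).
#' @param method Joint discretization scheme, see [discretize_2d()].
#' @param seed Seed for the `"cluster"` scheme.
#' @return A one-row tibble: `I1`, `I2`, `I12`, `syn`.
#' @export
synergy_score <- function(g1, g2, phenotype, n_states = 3,
                          method = c("grid", "cluster"), seed = 1) {
  method <- match.arg(method)
  stopifnot(length(g1) == length(g2))
  ph <- check_phenotype(phenotype, length(g1))
  i1 <- mutual_information(table(discretize_1d(g1, n_states), ph))
  i2 <- mutual_information(table(discretize_1d(g2, n_states), ph))
  i12 <- mutual_information(
    table(discretize_2d(g1, g2, n_states, method, seed), ph))
  tibble(I1 = i1, I2 = i2, I12 = i12, syn = i12 - i1 - i2)
}

# normalized MI for each label column of a 0/1 indicator matrix L (n x R),
# given integer states s (n); returns numeric vector length R.
# H(P) is identical across columns because each column is a permutation of
# the same labels.
mi_columns <- function(s, L) {
  n <- nrow(L)
  k <- max(s)
  S <- matrix(0, n, k)
  S[cbind(seq_len(n), s)] <- 1
  c1 <- crossprod(S, L)                 # k x R: counts in class 1
  rows <- colSums(S)                    # state totals
  c0 <- rows - c1
  n1 <- sum(L[, 1])
  h_p <- entropy_bits(c(n1, n - n1))
  if (h_p == 0) abort("degenerate phenotype: column entropy is zero")
  h_s <- entropy_bits(rows)
  h_sp <- -colSums(xlog2x(c1 / n) + xlog2x(c0 / n))
  pmax(h_s + h_p - h_sp, 0) / h_p
}

#' Permutation p-values for synergy scores
#'
#' One-sided empirical p-values for positive synergy: the phenotype labels
#' are randomly permuted `B` times (the same `B` permutations are reused for
#' every pair), the synergy score is recomputed under each permutation, and
#' `p = (1 + #\{b: syn_b >= syn_obs\}) / (B + 1)`. Ties count against
#' significance and the +1 smoothing keeps p strictly positive.
#'
#' This is exposed for completeness; [synergy_scan()] runs the same
#' computation vectorized across all pairs of a dataset.
#'
#' @param g1,g2 Expression vectors.
#' @param phenotype Two-class labels.
#' @param B Number of permutations (default 1000).
#' @param n_states,method,seed As in [synergy_score()].
#' @return A one-row tibble: `syn`, `p_raw`.
#' @export
permutation_test <- function(g1, g2, phenotype, B = 1000, n_states = 3,
                             method = c("grid", "cluster"), seed = 1) {
  method <- match.arg(method)
  if (B < 1) abort("B must be >= 1")
  ph <- check_phenotype(phenotype, length(g1))
  L <- permutation_labels(ph, B, seed)
  s1 <- discretize_1d(g1, n_states)
  s2 <- discretize_1d(g2, n_states)
  s12 <- discretize_2d(g1, g2, n_states, method, seed)
  syn_cols <- mi_columns(s12, L) - mi_columns(s1, L) - mi_columns(s2, L)
  tibble(syn = syn_cols[1],
         p_raw = (1 + sum(syn_cols[-1] >= syn_cols[1])) / (B + 1))
}

# n x (B+1) 0/1 indicator matrix: column 1 = observed labels (identity
# permutation), columns 2..B+1 = random permutations
permutation_labels <- function(ph, B, seed) {
  pos <- ph == positive_class(ph)
  L <- matrix(0, length(ph), B + 1)
  L[, 1] <- as.numeric(pos)
  with_substream(seed, {
    for (b in seq_len(B)) L[, b + 1] <- as.numeric(sample(pos))
  })
  L
}

positive_class <- function(ph) {
  lv <- sort(unique(ph))
  if ("toxic" %in% lv) "toxic" else lv[1]
}

#' Pairwise synergy scan over a dataset
#'
#' Computes the information synergy of every unordered gene pair with
#' respect to the phenotype, assesses significance by a shared-permutation
#' test, adjusts p-values once across all pairs by Benjamini-Hochberg, and
#' classifies positive-synergy pairs into joint-expression patterns
#' ([classify_pattern()]).
#'
#' @param dataset An `expr_dataset` with a two-class phenotype.
#' @param genes Optional subset of gene ids to scan (default: all).
#' @param B Number of phenotype permutations (default 1000).
#' @param alpha Significance level applied to adjusted p-values downstream
#'   (stored, used by [build_network()] as its default).
#' @param n_states,method As in [synergy_score()].
#' @param seed Seed driving the permutations (and the `"cluster"`
#'   discretization).
#' @return A `synergy_scan` object; `tidy()` returns the per-pair tibble
#'   (`gene1`, `gene2`, `I1`, `I2`, `I12`, `syn`, `p_raw`, `p_adj`,
#'   `pattern`), `glance()` a one-row summary.
#' @export
synergy_scan <- function(dataset, genes = NULL, B = 1000, alpha = 0.05,
                         n_states = 3, method = c("grid", "cluster"),
                         seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "expr_dataset"))
  if (B < 1) abort("B must be >= 1")
  if (is.null(genes)) genes <- rownames(dataset$values)
  missing <- setdiff(genes, rownames(dataset$values))
  if (length(missing)) abort(paste0("unknown gene: ", missing[1]))
  X <- dataset$values[genes, , drop = FALSE]
  ph <- check_phenotype(dataset$samples$phenotype, ncol(X))
  L <- permutation_labels(ph, B, seed)

  states1 <- lapply(seq_len(nrow(X)), function(i) {
    discretize_1d(X[i, ], n_states)
  })
  mi1 <- lapply(states1, mi_columns, L = L)

  pairs <- gene_pairs(genes)
  ii <- match(pairs$gene1, genes)
  jj <- match(pairs$gene2, genes)
  syn_obs <- numeric(nrow(pairs))
  i1 <- numeric(nrow(pairs)); i2 <- numeric(nrow(pairs))
  i12 <- numeric(nrow(pairs)); p_raw <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- ii[r]; b <- jj[r]
    s12 <- if (method == "grid") {
      joint <- (states1[[a]] - 1L) * max(states1[[b]]) + states1[[b]]
      match(joint, sort(unique(joint)))
    } else {
      discretize_2d(X[a, ], X[b, ], n_states, method, seed)
    }
    m12 <- mi_columns(s12, L)
    syn <- m12 - mi1[[a]] - mi1[[b]]
    i1[r] <- mi1[[a]][1]; i2[r] <- mi1[[b]][1]; i12[r] <- m12[1]
    syn_obs[r] <- syn[1]
    p_raw[r] <- (1 + sum(syn[-1] >= syn[1])) / (B + 1)
  }
  res <- pairs |>
    mutate(I1 = i1, I2 = i2, I12 = i12, syn = syn_obs,
           p_raw = p_raw, p_adj = bh_adjust(p_raw))
  res$pattern <- NA_character_
  pos <- which(res$syn > 0)
  for (r in pos) {
    res$pattern[r] <- classify_pattern(X[ii[r], ], X[jj[r], ], ph)
  }
  structure(list(pairs = res, genes = genes, B = B, alpha = alpha,
                 n_states = n_states, method = method, seed = seed,
                 n_samples = ncol(X),
                 phenotype = table(ph)),
            class = "synergy_scan")
}

#' @export
print.synergy_scan <- function(x, ...) {
  cat(sprintf("<synergy_scan> %d genes, %d pairs, B = %d permutations\n",
              length(x$genes), nrow(x$pairs), x$B))
  cat(sprintf("positive synergy: %d pairs; BH-significant at %.3g: %d\n",
              sum(x$pairs$syn > 0),
              x$alpha, sum(x$pairs$p_adj < x$alpha & x$pairs$syn > 0)))
  invisible(x)
}

#' Classify the joint-expression pattern of a cooperative pair
#'
#' Positive-synergy pairs fall into three joint-expression configurations:
#' \describe{
#'   \item{gap}{genes positively correlated, phenotype separated along the
#'     difference axis `(G1 - G2)/sqrt(2)`;}
#'   \item{substitute}{genes negatively correlated, phenotype separated
#'     along the sum axis `(G1 + G2)/sqrt(2)`;}
#'   \item{onoff}{both genes jointly silent in one phenotype and jointly
#'     active in the other, with neither linear axis separating the
#'     classes.}
#' }
#' The rule compares Welch t statistics of the phenotype along the two
#' axes; the winning axis must also separate the phenotypes (t-test
#' p < 0.05), otherwise the pattern is `"onoff"`.
#'
#' @param g1,g2 Expression vectors.
#' @param phenotype Two-class labels.
#' @return `"gap"`, `"substitute"` or `"onoff"`.
#' @export
classify_pattern <- function(g1, g2, phenotype) {
  ph <- check_phenotype(phenotype, length(g1))
  pos <- ph == positive_class(ph)
  r <- suppressWarnings(cor(g1, g2))
  if (is.na(r)) r <- 0
  d <- (g1 - g2) / sqrt(2)
  s <- (g1 + g2) / sqrt(2)
  t_of <- function(v) {
    tryCatch({
      tt <- t.test(v[pos], v[!pos])
      c(abs(tt$statistic), tt$p.value)
    }, error = function(e) c(0, 1))
  }
  td <- t_of(d); ts <- t_of(s)
  if (r >= 0 && td[1] > ts[1] && td[2] < 0.05) return("gap")
  if (r < 0 && ts[1] > td[1] && ts[2] < 0.05) return("substitute")
  "onoff"
}
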