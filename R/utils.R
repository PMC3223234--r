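#' All unordered gene pairs
#'
#' Enumerates the candidate pairs entering a synergy scan: every unordered
#' pair of distinct gene identifiers, `choose(length(genes), 2)` rows.
#'
#' @param genes Character vector of unique gene identifiers.
#' @return A tibble with columns `gene1`, `gene2` (`gene1` precedes `gene2`
#'   in the input order).
#' @examples
#' gene_pairs(c("a", "b", "c"))
#' @export
gene_pairs <- function(genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene id: ", genes[duplicated(genes)][1]))
  }
  n <- length(genes)
  if (n < 2) {
    return(tibble(gene1 = character(), gene2 = character()))
  }
  idx <- combn(n, 2)
  tibble(gene1 = genes[idx[1, ]], gene2 = genes[idx[2, ]])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a family of p-values.
#' Input order is preserved and adjusted values never fall below the raw
#' values. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    abort("all p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

# x * log2(x) with the 0 log 0 = 0 convention, elementwise
xlog2x <- function(x) {
  out <- x * log2(x)
  out[x == 0] <- 0
  out
}

# Shannon entropy (bits) of a count vector
entropy_bits <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) return(0)
  -sum(xlog2x(counts / tot))
}

# run expr with a private RNG stream; never touches the caller's RNG state
with_substream <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# check for a two-class phenotype vector; returns it as character
check_phenotype <- function(phenotype, n = NULL) {
  ph <- as.character(phenotype)
  if (!is.null(n) && length(ph) != n) {
    abort("phenotype length does not match number of samples")
  }
  if (length(unique(ph)) != 2) {
    abort("degenerate phenotype: exactly two classes required")
  }
  ph
}
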