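#' Construct an expression dataset
#'
#' Bundles a log2 expression matrix with per-sample condition and phenotype
#' labels. This is the container every analysis stage consumes.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene ids, column names sample ids (supplied separately via `samples`).
#' @param samples Data frame with columns `sample_id`, `condition`
#'   (`BSA`/`PA`/`OA` in the study design, but arbitrary labels are allowed),
#'   and `phenotype` (two classes, conventionally `toxic`/`nontoxic`), one
#'   row per column of `values`, in column order.
#' @param genes Optional data frame of per-gene annotation with a `gene_id`
#'   column matching the row names of `values` (the simulator stores the
#'   ground-truth roles here).
#' @return An object of class `expr_dataset`: a list with elements `values`,
#'   `samples` (tibble), `genes` (tibble).
#' @export
expr_dataset <- function(values, samples, genes = NULL) {
  values <- as.matrix(values)
  samples <- as_tibble(samples)
  req <- c("sample_id", "condition", "phenotype")
  if (!all(req %in% names(samples))) {
    abort(paste0("samples must have columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(samples) != ncol(values)) {
    abort("samples must have one row per column of `values`")
  }
  if (is.null(rownames(values))) abort("`values` must have gene ids as row names")
  if (anyDuplicated(rownames(values))) {
    abort(paste0("duplicate gene id: ",
                 rownames(values)[duplicated(rownames(values))][1]))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort(paste0("duplicate sample id: ",
                 samples$sample_id[duplicated(samples$sample_id)][1]))
  }
  if (anyNA(values)) abort("expression values must not contain missing values")
  colnames(values) <- samples$sample_id
  if (is.null(genes)) genes <- tibble(gene_id = rownames(values))
  genes <- as_tibble(genes)
  stopifnot(all(genes$gene_id == rownames(values)))
  structure(list(values = values, samples = samples, genes = genes),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("conditions: ",
      paste(sprintf("%s=%d", names(table(x$samples$condition)),
                    table(x$samples$condition)), collapse = ", "), "\n")
  cat("phenotypes: ",
      paste(sprintf("%s=%d", names(table(x$samples$phenotype)),
                    table(x$samples$phenotype)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Long-format view of an expression dataset
#'
#' @param x An `expr_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `condition`,
#'   `phenotype`, `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.expr_dataset <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(x$samples$sample_id, each = nrow(x$values)),
    condition = rep(x$samples$condition, each = nrow(x$values)),
    phenotype = rep(x$samples$phenotype, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}
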