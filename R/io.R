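#' Read an expression dataset from TSV files
#'
#' The expression file has a `gene_id` first column and one numeric column
#' per sample; the metadata file has columns `sample_id`, `condition`,
#' `phenotype`. Sample ids must match exactly (order taken from the
#' expression header).
#'
#' @param expr_path Path to the expression TSV.
#' @param samples_path Path to the sample-metadata TSV.
#' @return An [expr_dataset()].
#' @export
read_expression <- function(expr_path, samples_path) {
  expr <- readr::read_tsv(expr_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  if (names(expr)[1] != "gene_id") {
    abort("expression file must start with a `gene_id` column")
  }
  gene_ids <- expr$gene_id
  if (anyDuplicated(gene_ids)) {
    abort(paste0("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1]))
  }
  mat <- as.matrix(expr[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
    abort(sprintf("malformed numeric cell at gene %s, sample %s",
                  gene_ids[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  dimnames(num) <- list(gene_ids, colnames(mat))
  meta <- readr::read_tsv(samples_path, show_col_types = FALSE)
  req <- c("sample_id", "condition", "phenotype")
  if (!all(req %in% names(meta))) {
    abort(paste0("sample metadata must have columns: ",
                 paste(req, collapse = ", ")))
  }
  missing <- setdiff(colnames(num), meta$sample_id)
  if (length(missing)) {
    abort(paste0("sample missing from metadata: ", missing[1]))
  }
  extra <- setdiff(meta$sample_id, colnames(num))
  if (length(extra)) {
    abort(paste0("sample missing from expression: ", extra[1]))
  }
  meta <- meta[match(colnames(num), meta$sample_id), req]
  expr_dataset(num, meta)
}

#' Write an expression dataset to TSV files
#'
#' @param dataset An `expr_dataset`.
#' @param expr_path,samples_path Output paths.
#' @return Invisibly, the dataset.
#' @export
write_expression <- function(dataset, expr_path, samples_path) {
  stopifnot(inherits(dataset, "expr_dataset"))
  out <- bind_cols(tibble(gene_id = rownames(dataset$values)),
                   as_tibble(as.data.frame(dataset$values)))
  readr::write_tsv(out, expr_path)
  readr::write_tsv(dataset$samples, samples_path)
  invisible(dataset)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated -- name, description, then
#' member gene ids. Duplicate member ids within a set are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (set name -> member gene ids);
#'   descriptions are kept in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm)) {
    d <- nm[duplicated(nm)][1]
    lns <- which(nm == d)
    abort(sprintf("duplicate pathway name '%s' at GMT lines %s",
                  d, paste(lns, collapse = " and ")))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(fields, `[[`, "", 2), nm)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named descriptions; defaults to the set name.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path, description = NULL) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  if (is.null(description)) {
    description <- attr(gene_sets, "description")
  }
  lines <- vapply(names(gene_sets), function(nm) {
    desc <- if (!is.null(description) && nm %in% names(description)) {
      description[[nm]]
    } else nm
    paste(c(nm, desc, gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a network as a SIF-style edge list
#'
#' One line per edge: `gene1 <TAB> relation <TAB> gene2`.
#'
#' @param network A `gene_network`.
#' @param path Output path.
#' @param relation Interaction label (defaults to the network type,
#'   e.g. `"syn"`).
#' @return Invisibly, `path`.
#' @export
write_sif <- function(network, path, relation = NULL) {
  stopifnot(inherits(network, "gene_network"))
  if (is.null(relation)) {
    relation <- if (network$type == "synergy") "syn" else network$type
  }
  e <- network$edges
  writeLines(paste(e$gene1, relation, e$gene2, sep = "\t"), path)
  invisible(path)
}
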