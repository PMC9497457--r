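#' @title Expression matrix input/output
#'
#' @description An expression matrix is a numeric matrix of log2 expression
#' values with gene identifiers as rownames and sample identifiers as
#' colnames. On disk it is a TSV whose first column (\code{gene_id}) holds
#' the gene identifiers and whose header holds the sample identifiers.
#'
#' @param path Path to a tab-separated file.
#' @return \code{read_expression}: a numeric matrix (genes x samples).
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression TSV needs a gene_id column plus >=1 sample column")
  gene_ids <- as.character(tab[[1L]])
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric value in column '", sample_ids[j], "'",
           if (length(bad)) paste0(", row ", bad[1L], " (gene '", gene_ids[bad[1L]], "')"))
    }
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(gene_ids, sample_ids)
  validate_expression(m)
  m
}

#' @rdname expression_io
#' @param matrix Expression matrix (genes x samples) with dimnames.
#' @export
write_expression <- function(matrix, path) {
  validate_expression(matrix, allow_dup_genes = TRUE)
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(m, allow_dup_genes = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (!allow_dup_genes && anyDuplicated(rownames(m)))
    stop("duplicate gene ids (collapse_duplicate_genes first)")
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
  invisible(m)
}

#' Read or write a sample annotation table
#'
#' Sample annotations carry one row per sample with at least
#' \code{sample_id}, \code{group} (\code{case}/\code{control}) and
#' \code{batch}; derived labels (\code{subtype}, \code{pattern},
#' \code{lncrna_cluster}, \code{score_group}) are optional columns.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
  ann
}

#' @rdname read_annotation
#' @param annotation Annotation data.frame.
#' @export
write_annotation <- function(annotation, path) {
  validate_annotation(annotation)
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_annotation <- function(ann) {
  need <- c("sample_id", "group", "batch")
  miss <- setdiff(need, colnames(ann))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id in annotation")
  if (!all(ann$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  invisible(ann)
}

#' Collapse duplicated gene rows by the element-wise median
#'
#' When several rows map to the same gene identifier (e.g. several probes
#' per gene symbol), each gene's expression is taken as the per-sample
#' median over its rows. Row order follows the first occurrence of each
#' gene.
#'
#' @param matrix Expression matrix possibly containing repeated gene ids.
#' @return Expression matrix with unique gene ids.
#' @export
collapse_duplicate_genes <- function(matrix) {
  validate_expression(matrix, allow_dup_genes = TRUE)
  ids <- rownames(matrix)
  if (!anyDuplicated(ids)) return(matrix)
  keep <- unique(ids)
  out <- matrix(NA_real_, length(keep), ncol(matrix),
                dimnames = list(keep, colnames(matrix)))
  dup <- ids[duplicated(ids)]
  singles <- setdiff(keep, dup)
  out[singles, ] <- matrix[match(singles, ids), , drop = FALSE]
  for (g in unique(dup)) {
    out[g, ] <- apply(matrix[ids == g, , drop = FALSE], 2L, stats::median)
  }
  out
}

#' Merge multi-batch cohorts into one expression matrix
#'
#' Column-concatenates several expression matrices restricted to their
#' common gene set (matrices profiled on different platforms rarely share
#' the full gene universe) and records the batch of origin per sample.
#'
#' @param matrices List of expression matrices with disjoint sample ids.
#' @param batch_labels Character vector, one label per matrix.
#' @return List with \code{expression} (merged matrix) and
#'   \code{annotation} (data.frame of \code{sample_id}, \code{batch}).
#' @export
merge_cohorts <- function(matrices, batch_labels = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  if (is.null(batch_labels)) batch_labels <- paste0("batch", seq_along(matrices))
  if (length(batch_labels) != length(matrices))
    stop("need one batch label per matrix")
  lapply(matrices, validate_expression)
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (length(genes) == 0L) stop("empty gene intersection across cohorts")
  samples <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(samples))
    stop("clashing sample ids across cohorts: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  merged <- do.call(cbind, lapply(matrices, function(m) m[genes, , drop = FALSE]))
  batch <- rep(batch_labels, vapply(matrices, ncol, 1L))
  list(expression = merged,
       annotation = data.frame(sample_id = colnames(merged), batch = batch,
                               stringsAsFactors = FALSE))
}
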