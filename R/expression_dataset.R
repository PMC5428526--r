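#' Gene-by-cell expression dataset
#'
#' Container for a single-cell count matrix together with aligned gene and
#' cell annotation tables, a protocol tag and free-text provenance. Counts
#' are non-negative integers with genes as rows and cells as columns.
#'
#' The gene table carries one row per matrix row with columns `gene_id`,
#' `symbol`, `length_bp` (union-exon length in bp, `NA` when unknown),
#' `gene_class` (one of `ordinary`, `mito`, `ribo`, `spikein`) and `curated`
#' (whether the gene has a curated external identifier). The cell table
#' carries `cell_id`, `dataset_id`, `condition` and `batch`.
#'
#' @param counts integer matrix, genes x cells.
#' @param genes data frame aligned to rows, or a character vector of gene
#'   ids (remaining annotation columns are filled with defaults).
#' @param cells data frame aligned to columns, or a character vector of
#'   cell ids.
#' @param protocol `"full_length"` or `"umi"`.
#' @param provenance free-text description of where the counts came from.
#' @return An object of class `ExpressionDataset`.
#' @examples
#' counts <- matrix(c(1L, 0L, 2L, 3L), 2, 2,
#'                  dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' eds <- ExpressionDataset(counts, protocol = "umi")
#' dim(eds)
#' @export
ExpressionDataset <- function(counts, genes = NULL, cells = NULL,
                              protocol = c("full_length", "umi"),
                              provenance = "") {
  protocol <- match.arg(protocol)
  counts <- as.matrix(counts)
  if (is.null(genes)) genes <- rownames(counts)
  if (is.null(cells)) cells <- colnames(counts)
  if (is.character(genes) || is.null(genes)) {
    ids <- if (is.null(genes)) sprintf("G%05d", seq_len(nrow(counts))) else genes
    genes <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  }
  if (is.character(cells) || is.null(cells)) {
    ids <- if (is.null(cells)) sprintf("C%04d", seq_len(ncol(counts))) else cells
    cells <- data.frame(cell_id = ids, stringsAsFactors = FALSE)
  }
  genes <- .complete_gene_table(as.data.frame(genes))
  cells <- .complete_cell_table(as.data.frame(cells))
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cells$cell_id
  x <- structure(
    list(counts = counts, genes = genes, cells = cells,
         protocol = protocol, provenance = provenance),
    class = "ExpressionDataset")
  validate_dataset(x)
  x
}

.complete_gene_table <- function(genes) {
  stopifnot("gene_id" %in% names(genes))
  n <- nrow(genes)
  genes$gene_id <- as.character(genes$gene_id)
  if (is.null(genes$symbol)) genes$symbol <- genes$gene_id
  if (is.null(genes$length_bp)) genes$length_bp <- rep(NA_integer_, n)
  if (is.null(genes$gene_class)) genes$gene_class <- rep("ordinary", n)
  if (is.null(genes$curated)) genes$curated <- rep(TRUE, n)
  genes$symbol <- as.character(genes$symbol)
  genes$length_bp <- as.integer(round(as.numeric(genes$length_bp)))
  genes$gene_class <- as.character(genes$gene_class)
  genes$curated <- as.logical(genes$curated)
  rownames(genes) <- NULL
  genes
}

.complete_cell_table <- function(cells) {
  stopifnot("cell_id" %in% names(cells))
  n <- nrow(cells)
  cells$cell_id <- as.character(cells$cell_id)
  if (is.null(cells$dataset_id)) cells$dataset_id <- rep("dataset1", n)
  if (is.null(cells$condition)) cells$condition <- rep("unknown", n)
  if (is.null(cells$batch)) cells$batch <- rep("batch1", n)
  rownames(cells) <- NULL
  cells
}

#' Validate an ExpressionDataset
#'
#' Checks the container invariants: aligned dimensions, non-negative
#' integral counts, a valid gene-class label per gene, spike-in records
#' never classed mito/ribo, positive lengths where present, and unique
#' cell ids within each dataset.
#'
#' @param x an `ExpressionDataset`.
#' @return `x`, invisibly; stops with a message on violation.
#' @export
validate_dataset <- function(x) {
  stopifnot(inherits(x, "ExpressionDataset"))
  if (nrow(x$counts) != nrow(x$genes))
    stop("row count (", nrow(x$counts), ") != number of gene records (",
         nrow(x$genes), ")")
  if (ncol(x$counts) != nrow(x$cells))
    stop("column count (", ncol(x$counts), ") != number of cell records (",
         nrow(x$cells), ")")
  bad <- which(x$counts < 0 | x$counts != round(x$counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-integer or negative count ", x$counts[bad[1, 1], bad[1, 2]],
         " at gene ", bad[1, 1], ", cell ", bad[1, 2])
  ok_class <- x$genes$gene_class %in% c("ordinary", "mito", "ribo", "spikein")
  if (!all(ok_class))
    stop("invalid gene_class: ", paste(unique(x$genes$gene_class[!ok_class]),
                                       collapse = ", "))
  len <- x$genes$length_bp
  if (any(!is.na(len) & len < 1))
    stop("length_bp must be >= 1 when present")
  dup <- duplicated(paste(x$cells$dataset_id, x$cells$cell_id))
  if (any(dup))
    stop("duplicate cell_id within a dataset: ",
         paste(unique(x$cells$cell_id[dup]), collapse = ", "))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d cells (%s protocol)\n",
              nrow(x$counts), ncol(x$counts), x$protocol))
  cls <- table(factor(x$genes$gene_class,
                      levels = c("ordinary", "mito", "ribo", "spikein")))
  cat("  gene classes:", paste(names(cls), cls, sep = "=", collapse = " "), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# Subset genes (rows) and/or cells (columns), preserving order of survivors.
subset_dataset <- function(x, genes = NULL, cells = NULL) {
  if (!is.null(genes)) {
    x$counts <- x$counts[genes, , drop = FALSE]
    x$genes <- x$genes[genes, , drop = FALSE]
    rownames(x$genes) <- NULL
  }
  if (!is.null(cells)) {
    x$counts <- x$counts[, cells, drop = FALSE]
    x$cells <- x$cells[cells, , drop = FALSE]
    rownames(x$cells) <- NULL
  }
  x
}
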