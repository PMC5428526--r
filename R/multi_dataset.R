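#' Genes detected in a dataset
#'
#' A gene counts as detected when it has a nonzero count in at least
#' `ceiling(min_cell_fraction * n_cells)` cells, so the criterion reads
#' "at least 10% of the cells" at the default fraction.
#'
#' @param dataset a filtered [ExpressionDataset].
#' @param min_cell_fraction detection fraction (default 0.10).
#' @return Character vector of detected gene ids (matrix order).
#' @export
detected_gene_set <- function(dataset, min_cell_fraction = 0.10) {
  stopifnot(min_cell_fraction >= 0, min_cell_fraction <= 1)
  thr <- ceiling(min_cell_fraction * ncol(dataset$counts))
  dataset$genes$gene_id[rowSums(dataset$counts > 0) >= thr]
}

#' Genes commonly detected across datasets
#'
#' Intersects the per-dataset detected sets so that no dataset dominates
#' gene selection, and orders the result lexicographically.
#'
#' @param datasets list of two or more [ExpressionDataset]s.
#' @param min_cell_fraction detection fraction (default 0.10).
#' @return Sorted character vector; empty (with a warning) when no gene is
#'   detected everywhere.
#' @export
common_genes <- function(datasets, min_cell_fraction = 0.10) {
  if (length(datasets) < 2) stop("need at least two datasets")
  sets <- lapply(datasets, detected_gene_set, min_cell_fraction)
  out <- sort(Reduce(intersect, sets))
  if (length(out) == 0) warning("no gene detected in every dataset")
  out
}

#' Combine datasets on a shared gene list
#'
#' Restricts every dataset to `genes` (in the supplied order) and
#' column-concatenates the matrices. Cell records keep their `dataset_id`
#' and gain a `protocol` column recording the source protocol.
#'
#' @param datasets list of [ExpressionDataset]s.
#' @param genes ordered gene ids present in every dataset.
#' @return A combined [ExpressionDataset] (protocol tag `"full_length"` is
#'   nominal; per-cell protocols live in the cell table).
#' @export
combine_datasets <- function(datasets, genes) {
  blocks <- lapply(datasets, function(d) {
    idx <- match(genes, d$genes$gene_id)
    if (anyNA(idx))
      stop("gene ", genes[which(is.na(idx))[1]], " missing from dataset '",
           d$cells$dataset_id[1], "'")
    d$counts[idx, , drop = FALSE]
  })
  cells <- do.call(rbind, lapply(datasets, function(d) {
    tab <- d$cells[, c("cell_id", "dataset_id", "condition", "batch")]
    tab$protocol <- d$protocol
    tab
  }))
  ref <- datasets[[1]]
  gtab <- ref$genes[match(genes, ref$genes$gene_id), , drop = FALSE]
  combined <- ExpressionDataset(do.call(cbind, blocks), gtab, cells,
                                protocol = ref$protocol,
                                provenance = paste0("combined from ",
                                                    length(datasets),
                                                    " datasets"))
  combined
}

#' PCA embedding of cells
#'
#' Centers each column (gene) of a cells x genes log-expression matrix and
#' takes the singular value decomposition. Coordinates are the projections
#' onto the first components; component variances are `d^2 / (n - 1)`,
#' non-increasing. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive.
#'
#' @param log_expr cells x genes real matrix.
#' @param n_components number of components to return.
#' @return List with `coordinates` (cells x k), `variance` (length k) and
#'   `loadings` (genes x k).
#' @export
pca_embedding <- function(log_expr, n_components = 2) {
  log_expr <- as.matrix(log_expr)
  k <- n_components
  if (k < 1) stop("n_components must be >= 1")
  if (k > min(dim(log_expr)))
    stop("n_components exceeds min(cells, genes)")
  xc <- scale(log_expr, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  u <- sweep(sv$u, 2, flip, "*")
  v <- sweep(sv$v, 2, flip, "*")
  coords <- sweep(u, 2, sv$d[seq_len(k)], "*")
  rownames(coords) <- rownames(log_expr)
  colnames(coords) <- paste0("PC", seq_len(k))
  rownames(v) <- colnames(log_expr)
  colnames(v) <- paste0("PC", seq_len(k))
  list(coordinates = coords,
       variance = sv$d[seq_len(k)]^2 / (nrow(log_expr) - 1),
       loadings = v)
}

#' Detection overlap between two protocol groups
#'
#' Each group's detected set is the intersection of the per-dataset
#' detected sets within the group ("detected in both"); the universe is
#' the union of all per-dataset detected sets across the two groups. The
#' Venn regions are computed from the two group sets.
#'
#' @param group_a,group_b lists of [ExpressionDataset]s (at least one each).
#' @param min_cell_fraction detection fraction (default 0.10).
#' @return List of class `DetectionOverlap` with counts (`universe_size`,
#'   `in_both`, `only_a`, `only_b`) and sorted membership vectors
#'   (`genes_in_both`, `genes_only_a`, `genes_only_b`).
#' @export
detection_overlap <- function(group_a, group_b, min_cell_fraction = 0.10) {
  if (length(group_a) < 1 || length(group_b) < 1)
    stop("each group needs at least one dataset")
  per_set <- function(group)
    lapply(group, detected_gene_set, min_cell_fraction)
  sets_a <- per_set(group_a); sets_b <- per_set(group_b)
  set_a <- Reduce(intersect, sets_a)
  set_b <- Reduce(intersect, sets_b)
  universe <- Reduce(union, c(sets_a, sets_b))
  structure(list(
    universe_size = length(universe),
    in_both = length(intersect(set_a, set_b)),
    only_a = length(setdiff(set_a, set_b)),
    only_b = length(setdiff(set_b, set_a)),
    genes_in_both = sort(intersect(set_a, set_b)),
    genes_only_a = sort(setdiff(set_a, set_b)),
    genes_only_b = sort(setdiff(set_b, set_a)),
    universe = sort(universe)), class = "DetectionOverlap")
}

#' @export
print.DetectionOverlap <- function(x, ...) {
  cat(sprintf(paste0("DetectionOverlap: universe %d genes | in both %d | ",
                     "only group A %d | only group B %d\n"),
              x$universe_size, x$in_both, x$only_a, x$only_b))
  invisible(x)
}
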