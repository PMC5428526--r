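#' Median-of-ratios size factors
#'
#' Per-cell scaling factors that correct depth and composition differences:
#' each cell's factor is the median, over reference genes (genes expressed
#' in every cell), of the ratio of the cell's count to the gene's
#' geometric mean across cells. Factors are rescaled to geometric mean 1.
#' When no gene is expressed in all cells the factors fall back to
#' library-size ratios, with a warning.
#'
#' @param counts genes x cells integer matrix.
#' @return Positive numeric vector of length `ncol(counts)` with geometric
#'   mean 1.
#' @export
median_ratio_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    warning("no gene expressed in every cell; using library-size factors")
    lib <- colSums(counts)
    if (any(lib == 0)) stop("cell with zero library size")
    sf <- lib
  } else {
    logc <- log(counts[ref, , drop = FALSE])
    logratios <- logc - rowMeans(logc)
    sf <- exp(apply(logratios, 2, stats::median))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Two-group differential expression
#'
#' A dependency-light stand-in preserving the published analysis design
#' (normalize, test, apply a log-fold-change cut-off, control FDR):
#' counts are scaled by size factors and converted to normalized CPM with
#' a common library size, the per-gene log2 fold change is the difference
#' of group means of `log2(CPM + pseudocount)`, the p-value comes from the
#' Wilcoxon rank-sum test on the normalized log expression, and
#' Benjamini-Hochberg adjustment is applied across genes. A gene is called
#' significant when `fdr <= alpha` and `|log2 fold change| >= lfc_cutoff`.
#'
#' @param dataset an [ExpressionDataset].
#' @param group optional two-level factor over cells; defaults to the cell
#'   table's `condition` column. Fold changes are level 2 vs level 1.
#' @param lfc_cutoff absolute log2-fold-change threshold applied post hoc
#'   (1 is typical for deep full-length data, 0.5 for shallow UMI data).
#' @param alpha FDR level (default 0.05).
#' @param size_factors optional per-cell factors; default
#'   [median_ratio_size_factors()].
#' @param pseudocount log offset (default 1).
#' @return data frame with `gene_id`, `log2_fold_change`, `p_value`,
#'   `fdr`, `significant`.
#' @export
de_two_group <- function(dataset, group = NULL, lfc_cutoff = 0, alpha = 0.05,
                         size_factors = NULL, pseudocount = 1) {
  counts <- dataset$counts
  if (is.null(group)) group <- dataset$cells$condition
  group <- factor(group)
  if (nlevels(group) != 2)
    stop("group must have exactly two levels, got: ",
         paste(levels(group), collapse = ", "))
  if (any(table(group) < 2)) stop("each group needs at least 2 cells")
  if (is.null(size_factors)) size_factors <- median_ratio_size_factors(counts)
  norm <- sweep(counts, 2, size_factors, "/")
  logx <- log2(norm / mean(colSums(norm)) * 1e6 + pseudocount)
  i1 <- which(group == levels(group)[1])
  i2 <- which(group == levels(group)[2])
  lfc <- rowMeans(logx[, i2, drop = FALSE]) -
    rowMeans(logx[, i1, drop = FALSE])
  p <- vapply(seq_len(nrow(logx)), function(g)
    wilcoxon_rank_sum(logx[g, i2], logx[g, i1])$p_value, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = dataset$genes$gene_id,
             log2_fold_change = lfc, p_value = p, fdr = fdr,
             significant = fdr <= alpha & abs(lfc) >= lfc_cutoff,
             stringsAsFactors = FALSE)
}

#' Fraction of a gene set called differentially expressed
#'
#' @param de data frame from [de_two_group()].
#' @param gene_set non-empty subset of the tested gene ids.
#' @return List with `set_fraction` (significant within the set),
#'   `overall_fraction` (significant among all tested genes) and the
#'   underlying counts.
#' @export
de_fraction_in_set <- function(de, gene_set) {
  if (length(gene_set) == 0) stop("gene_set is empty")
  if (!all(gene_set %in% de$gene_id))
    stop("gene_set contains untested genes")
  sig <- de$gene_id[de$significant]
  list(set_fraction = length(intersect(sig, gene_set)) / length(gene_set),
       overall_fraction = length(sig) / nrow(de),
       n_set_significant = length(intersect(sig, gene_set)),
       n_set = length(gene_set),
       n_significant = length(sig),
       n_tested = nrow(de))
}
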