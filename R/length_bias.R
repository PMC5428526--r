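#' Log counts per million
#'
#' Depth-normalizes each cell to counts per million and applies
#' `log2(x + pseudocount)`. Library sizes default to the column sums of
#' the supplied (post-filter) matrix but can be passed explicitly, e.g. to
#' exclude spike-in rows from the denominator.
#'
#' @param counts genes x cells integer matrix.
#' @param pseudocount positive offset added before logging (default 1, so
#'   a zero count maps to 0).
#' @param scale per-cell total after normalization (default 1e6).
#' @param lib_size optional per-cell library sizes.
#' @return Real matrix of the same shape.
#' @export
log_cpm <- function(counts, pseudocount = 1, scale = 1e6, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  zero <- which(lib_size == 0)
  if (length(zero) > 0)
    stop("zero library size for cell ",
         paste(colnames(counts)[zero[1]], collapse = ""), " (column ",
         zero[1], ")")
  log2(sweep(counts, 2, lib_size / scale, "/") + pseudocount)
}

#' Reads per kilobase per million
#'
#' Divides depth-normalized counts by gene length in kb:
#' `count / (lib_size/1e6) / (length_bp/1000)`. For genes of length
#' 1000 bp, RPKM equals CPM exactly. With `log = TRUE` returns
#' `log2(RPKM + pseudocount)`.
#'
#' @param counts genes x cells integer matrix.
#' @param lengths per-gene length in bp, aligned to rows; must be complete.
#' @param lib_size optional per-cell library sizes (default column sums).
#' @param log return `log2(RPKM + pseudocount)` instead of raw RPKM.
#' @param pseudocount offset for the log version.
#' @return Real matrix of the same shape.
#' @export
rpkm <- function(counts, lengths, lib_size = NULL, log = FALSE,
                 pseudocount = 1) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("lengths must have one entry per gene")
  if (anyNA(lengths))
    stop("missing gene length for ",
         paste(utils::head(rownames(counts)[is.na(lengths)], 3),
               collapse = ", "))
  if (is.null(lib_size)) lib_size <- colSums(counts)
  zero <- which(lib_size == 0)
  if (length(zero) > 0)
    stop("zero library size for cell (column ", zero[1], ")")
  out <- sweep(counts, 2, lib_size / 1e6, "/") / (lengths / 1000)
  if (log) log2(out + pseudocount) else out
}

#' Assign genes to equal-occupancy length bins
#'
#' Genes are sorted by `(length, gene_id)` and split into `n_bins`
#' contiguous groups whose sizes differ by at most one; when the gene
#' count is not divisible by `n_bins` the last bins take the extra gene.
#' Bin 1 holds the shortest genes. The gene-id tiebreak makes the
#' assignment deterministic under equal lengths.
#'
#' @param lengths per-gene lengths in bp; names (or `gene_ids`) break ties.
#' @param n_bins number of bins (default 10).
#' @param gene_ids optional ids aligned to `lengths`.
#' @return Integer vector of bin ids (1 = shortest) in input order.
#' @export
assign_length_bins <- function(lengths, n_bins = 10, gene_ids = names(lengths)) {
  n <- length(lengths)
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (n_bins > n) stop("n_bins (", n_bins, ") exceeds number of genes (", n, ")")
  if (anyNA(lengths)) stop("lengths must be complete")
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(n))
  ord <- order(lengths, gene_ids)
  sizes <- rep(n %/% n_bins, n_bins)
  r <- n %% n_bins
  if (r > 0) sizes[(n_bins - r + 1):n_bins] <- sizes[(n_bins - r + 1):n_bins] + 1L
  out <- integer(n)
  out[ord] <- rep(seq_len(n_bins), sizes)
  out
}

#' Per-gene expression and dropout summaries
#'
#' For each gene: the mean over cells of log2 CPM, the dropout rate
#' (fraction of cells with a zero count), the mean over cells of log2
#' RPKM, the length and the length-bin id. Library sizes exclude spike-in
#' rows by default, since spike-in content varies by protocol. The
#' `average` switch selects between averaging the per-cell log values
#' (default) and logging the per-gene average CPM.
#'
#' @param dataset a filtered [ExpressionDataset].
#' @param pseudocount log offset (default 1).
#' @param n_bins number of length bins (default 10); `NA` lengths get an
#'   `NA` bin.
#' @param exclude_spikeins_from_libsize exclude spike-in rows from the
#'   library-size denominator.
#' @param average `"mean_log"` (mean of `log2(CPM+pc)`) or `"log_mean"`
#'   (`log2(mean CPM + pc)`).
#' @return data frame with columns `gene_id`, `length_bp`, `mean_log_cpm`,
#'   `dropout_rate`, `mean_log_rpkm`, `bin_id`.
#' @export
gene_summaries <- function(dataset, pseudocount = 1, n_bins = 10,
                           exclude_spikeins_from_libsize = TRUE,
                           average = c("mean_log", "log_mean")) {
  average <- match.arg(average)
  validate_dataset(dataset)
  counts <- dataset$counts
  g <- dataset$genes
  endo <- if (exclude_spikeins_from_libsize) g$gene_class != "spikein" else
    rep(TRUE, nrow(g))
  lib <- colSums(counts[endo, , drop = FALSE])
  zero <- which(lib == 0)
  if (length(zero) > 0)
    stop("zero library size for cell ", dataset$cells$cell_id[zero[1]])
  cpm <- sweep(counts, 2, lib / 1e6, "/")
  len <- g$length_bp
  rpk <- cpm / (len / 1000)  # rows with NA length become NA
  if (average == "mean_log") {
    mlc <- rowMeans(log2(cpm + pseudocount))
    mlr <- rowMeans(log2(rpk + pseudocount))
  } else {
    mlc <- log2(rowMeans(cpm) + pseudocount)
    mlr <- log2(rowMeans(rpk) + pseudocount)
  }
  bin <- rep(NA_integer_, nrow(g))
  has_len <- !is.na(len)
  if (sum(has_len) >= n_bins)
    bin[has_len] <- assign_length_bins(len[has_len], n_bins,
                                       g$gene_id[has_len])
  data.frame(gene_id = g$gene_id, length_bp = len,
             mean_log_cpm = mlc, dropout_rate = rowMeans(counts == 0),
             mean_log_rpkm = mlr, bin_id = bin,
             stringsAsFactors = FALSE)
}

#' Per-bin medians and quartiles
#'
#' Summarizes the three per-gene statistics within each length bin:
#' lower quartile, median and upper quartile (linear-interpolation
#' quantiles), plus bin occupancy and length range. These are the numbers
#' behind the three boxplot panels (log counts, dropout rate, log RPKM)
#' per length bin.
#'
#' @param summaries data frame from [gene_summaries()].
#' @return data frame with one row per bin.
#' @export
bin_summaries <- function(summaries) {
  s <- summaries[!is.na(summaries$bin_id), , drop = FALSE]
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE,
                                    na.rm = TRUE)
  do.call(rbind, lapply(split(s, s$bin_id), function(b) {
    qc <- qs(b$mean_log_cpm); qd <- qs(b$dropout_rate); qr <- qs(b$mean_log_rpkm)
    data.frame(bin_id = b$bin_id[1], n_genes = nrow(b),
               length_min = min(b$length_bp), length_max = max(b$length_bp),
               cpm_q25 = qc[1], cpm_median = qc[2], cpm_q75 = qc[3],
               dropout_q25 = qd[1], dropout_median = qd[2], dropout_q75 = qd[3],
               rpkm_q25 = qr[1], rpkm_median = qr[2], rpkm_q75 = qr[3])
  }))
}

# Spearman rank correlation with midranks for ties and the large-sample
# t approximation for the p-value. Returns NA for a constant vector.
spearman_trend <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) == 1) return(c(rho = rho, p = 0))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(t), n - 2))
}

#' Length-bias trend statistics
#'
#' Quantifies the length trends visible in the binned boxplots as Spearman
#' rank correlations of gene length against each per-gene statistic
#' (mean log CPM, dropout rate, mean log RPKM), with large-sample
#' t-approximation p-values. Under a fragmentation-based protocol the
#' count correlation is positive and the dropout correlation negative;
#' under molecule counting both are near zero and dividing by length
#' drives the RPKM correlation negative.
#'
#' @param summaries data frame from [gene_summaries()]; needs >= 10 genes
#'   with lengths.
#' @return One-row data frame with `rho_count`, `rho_dropout`, `rho_rpkm`
#'   and their p-values; a constant statistic yields `NA`.
#' @export
length_bias_statistics <- function(summaries) {
  s <- summaries[!is.na(summaries$length_bp), , drop = FALSE]
  if (nrow(s) < 10) stop("need at least 10 genes with lengths")
  a <- spearman_trend(s$length_bp, s$mean_log_cpm)
  b <- spearman_trend(s$length_bp, s$dropout_rate)
  d <- spearman_trend(s$length_bp, s$mean_log_rpkm)
  data.frame(n_genes = nrow(s),
             rho_count = a[["rho"]], p_count = a[["p"]],
             rho_dropout = b[["rho"]], p_dropout = b[["p"]],
             rho_rpkm = d[["rho"]], p_rpkm = d[["p"]])
}

#' Boxplot panels of the per-bin summaries
#'
#' Draws the three-panel figure (mean log CPM, dropout rate, mean log
#' RPKM per length bin) from per-gene summaries using ggplot2.
#'
#' @param summaries data frame from [gene_summaries()].
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_length_bias <- function(summaries, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  s <- summaries[!is.na(summaries$bin_id), , drop = FALSE]
  long <- rbind(
    data.frame(bin = s$bin_id, value = s$mean_log_cpm, panel = "mean log2 CPM"),
    data.frame(bin = s$bin_id, value = s$dropout_rate, panel = "dropout rate"),
    data.frame(bin = s$bin_id, value = s$mean_log_rpkm, panel = "mean log2 RPKM"))
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$bin), .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "gene length bin (1 = shortest)", y = NULL,
                  title = title) +
    ggplot2::theme_bw()
}
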