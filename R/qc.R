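#' Per-cell quality-control metrics
#'
#' For every cell: the dropout fraction (share of genes in the matrix with
#' a zero count, spike-ins included), the library size (total counts) and
#' the spike-in fraction (spike-in counts over total counts; defined as 0
#' for an all-zero cell).
#'
#' @param dataset an [ExpressionDataset] with gene classes assigned.
#' @return data frame with columns `cell_id`, `dropout_fraction`,
#'   `library_size`, `spikein_fraction`.
#' @export
compute_cell_metrics <- function(dataset) {
  validate_dataset(dataset)
  counts <- dataset$counts
  lib <- colSums(counts)
  sp <- dataset$genes$gene_class == "spikein"
  sp_counts <- if (any(sp)) colSums(counts[sp, , drop = FALSE]) else
    numeric(ncol(counts))
  data.frame(
    cell_id = dataset$cells$cell_id,
    dropout_fraction = colMeans(counts == 0),
    library_size = lib,
    spikein_fraction = ifelse(lib > 0, sp_counts / lib, 0),
    stringsAsFactors = FALSE)
}

#' Cell quality-control thresholds
#'
#' Every published filter is phrased as a removal rule ("more than X%
#' dropout", "fewer than Y reads"), so cells equal to a threshold are
#' retained. `max_spikein_fraction = NA` disables the spike-in cap.
#'
#' @param max_dropout retain cells with dropout fraction `<=` this value.
#' @param min_library_size retain cells with library size `>=` this value.
#' @param max_spikein_fraction retain cells with spike-in fraction `<=`
#'   this value, or `NA` for no cap.
#' @return List of class `QCThresholds`.
#' @export
qc_thresholds <- function(max_dropout = 1, min_library_size = 0,
                          max_spikein_fraction = NA_real_) {
  stopifnot(max_dropout >= 0, max_dropout <= 1, min_library_size >= 0,
            is.na(max_spikein_fraction) ||
              (max_spikein_fraction >= 0 && max_spikein_fraction <= 1))
  structure(list(max_dropout = max_dropout,
                 min_library_size = min_library_size,
                 max_spikein_fraction = max_spikein_fraction),
            class = "QCThresholds")
}

#' Named per-dataset QC threshold presets
#'
#' The cell-filter settings used for each of the eight published datasets
#' (dropout cap / library-size floor / spike-in cap). `"ziegenhain"`
#' applies no cell filter. The Kolodziejczyk plate-level spike-in review
#' has no numeric criterion and is served by [batch_spikein_summary()]
#' instead of an automatic rule.
#'
#' @param name one of `"kolodziejczyk"`, `"guo"`, `"camp"`, `"grun"`,
#'   `"tung"`, `"klein"`, `"ziegenhain"`, `"buettner"`.
#' @return A [qc_thresholds()] object.
#' @export
qc_preset <- function(name) {
  presets <- list(
    kolodziejczyk = qc_thresholds(0.80, 5e5, NA),
    guo           = qc_thresholds(0.85, 5e5, NA),
    camp          = qc_thresholds(0.90, 5e5, 0.20),
    grun          = qc_thresholds(0.80, 1e4, 0.05),
    tung          = qc_thresholds(0.70, 3e4, 0.03),
    klein         = qc_thresholds(0.85, 1e4, 0.01),
    ziegenhain    = qc_thresholds(1.00, 0,   NA),
    buettner      = qc_thresholds(0.85, 1e6, NA))
  if (!name %in% names(presets))
    stop("unknown QC preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Per-batch spike-in content summary
#'
#' Summarizes the spike-in read fraction per batch (e.g. plate) so that
#' batches with excessive spike-in content can be reviewed and excluded by
#' the analyst.
#'
#' @param dataset an [ExpressionDataset].
#' @return data frame with one row per batch: number of cells, median and
#'   mean spike-in fraction.
#' @export
batch_spikein_summary <- function(dataset) {
  m <- compute_cell_metrics(dataset)
  sp <- split(m$spikein_fraction, dataset$cells$batch)
  data.frame(batch = names(sp),
             n_cells = lengths(sp),
             median_spikein_fraction = vapply(sp, stats::median, numeric(1)),
             mean_spikein_fraction = vapply(sp, mean, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter cells on QC metrics
#'
#' Retains cells with `dropout_fraction <= max_dropout`, `library_size >=
#' min_library_size` and, when a cap is set, `spikein_fraction <=
#' max_spikein_fraction`. Survivor order is preserved; the gene table is
#' unchanged.
#'
#' @param dataset an [ExpressionDataset].
#' @param thresholds a [qc_thresholds()] object.
#' @return The filtered dataset. A removal log is attached as attribute
#'   `"filter_log"`; removing every cell produces a valid empty dataset
#'   plus a warning.
#' @export
filter_cells <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "QCThresholds"))
  m <- compute_cell_metrics(dataset)
  ok_drop <- m$dropout_fraction <= thresholds$max_dropout
  ok_lib <- m$library_size >= thresholds$min_library_size
  ok_sp <- if (is.na(thresholds$max_spikein_fraction)) rep(TRUE, nrow(m)) else
    m$spikein_fraction <= thresholds$max_spikein_fraction
  keep <- ok_drop & ok_lib & ok_sp
  if (!any(keep)) warning("cell filter removed every cell")
  out <- subset_dataset(dataset, cells = which(keep))
  log <- c(attr(dataset, "filter_log"),
           list(cells_before = nrow(m),
                cells_retained = sum(keep),
                cells_removed_dropout = sum(!ok_drop),
                cells_removed_library = sum(!ok_lib),
                cells_removed_spikein = sum(!ok_sp)))
  attr(out, "filter_log") <- log
  out
}

#' Gene filter policy
#'
#' Defaults follow the study-wide rule set: drop genes with more than 90%
#' zeroes across cells, drop mitochondrial and ribosomal genes, require a
#' curated identifier and a known gene length. Spike-in genes are always
#' removed from the analysis matrix (their per-cell totals are kept on the
#' cell table for provenance).
#'
#' @param max_zero_fraction genes with zero-fraction strictly greater than
#'   this are removed.
#' @param excluded_classes gene classes removed outright.
#' @param require_curated drop genes without a curated identifier.
#' @param require_length drop genes with missing `length_bp`.
#' @return List of class `GeneFilterPolicy`.
#' @export
gene_filter_policy <- function(max_zero_fraction = 0.90,
                               excluded_classes = c("mito", "ribo"),
                               require_curated = TRUE,
                               require_length = TRUE) {
  stopifnot(max_zero_fraction >= 0, max_zero_fraction <= 1,
            all(excluded_classes %in% c("ordinary", "mito", "ribo", "spikein")))
  structure(list(max_zero_fraction = max_zero_fraction,
                 excluded_classes = excluded_classes,
                 require_curated = require_curated,
                 require_length = require_length),
            class = "GeneFilterPolicy")
}

#' Filter genes under a policy
#'
#' Zero fractions are computed on the cells present in `dataset`, so cell
#' filtering should be applied first. A gene with zero-fraction exactly at
#' the cap is retained (the rule removes "more than" the cap).
#'
#' @param dataset an [ExpressionDataset], usually cell-filtered.
#' @param policy a [gene_filter_policy()].
#' @return The filtered dataset with spike-in totals appended to the cell
#'   table (`spikein_counts`) and a removal log in attribute
#'   `"filter_log"`.
#' @export
filter_genes <- function(dataset, policy = gene_filter_policy()) {
  stopifnot(inherits(policy, "GeneFilterPolicy"))
  g <- dataset$genes
  zero_frac <- if (ncol(dataset$counts) > 0)
    rowMeans(dataset$counts == 0) else rep(0, nrow(dataset$counts))
  is_spike <- g$gene_class == "spikein"
  rm_zero <- zero_frac > policy$max_zero_fraction
  rm_class <- g$gene_class %in% setdiff(policy$excluded_classes, "spikein")
  rm_uncur <- if (policy$require_curated) !g$curated else logical(nrow(g))
  rm_nolen <- if (policy$require_length) is.na(g$length_bp) else logical(nrow(g))
  keep <- !(rm_zero | rm_class | rm_uncur | rm_nolen | is_spike)
  out <- subset_dataset(dataset, genes = which(keep))
  if (any(is_spike)) {
    out$cells$spikein_counts <-
      colSums(dataset$counts[is_spike, , drop = FALSE])
    out$provenance <- paste0(out$provenance, " [", sum(is_spike),
                             " spike-in genes removed from analysis matrix]")
  }
  log <- c(attr(dataset, "filter_log"),
           list(genes_before = nrow(g),
                genes_retained = sum(keep),
                genes_removed_zero_fraction = sum(rm_zero),
                genes_removed_class = sum(rm_class),
                genes_removed_spikein = sum(is_spike),
                genes_removed_uncurated = sum(rm_uncur),
                genes_removed_no_length = sum(rm_nolen)))
  attr(out, "filter_log") <- log
  out
}

#' Summarize filtering between two dataset states
#'
#' Builds a one-column summary of cells/genes retained and, when the
#' filtered dataset carries a removal log, the per-criterion removal
#' counts. Criterion counts are independent predicates, so one gene can be
#' counted under several criteria.
#'
#' @param before dataset before filtering.
#' @param after dataset after filtering.
#' @return data frame with columns `metric` and `value`.
#' @export
qc_report <- function(before, after) {
  base <- list(
    cells_before = ncol(before$counts),
    cells_after = ncol(after$counts),
    cells_removed = ncol(before$counts) - ncol(after$counts),
    genes_before = nrow(before$counts),
    genes_after = nrow(after$counts),
    genes_removed = nrow(before$counts) - nrow(after$counts))
  log <- attr(after, "filter_log")
  keep <- setdiff(names(log), c("cells_before", "genes_before",
                                "cells_retained", "genes_retained"))
  vals <- c(base, log[keep])
  data.frame(metric = names(vals), value = as.numeric(unlist(vals)),
             stringsAsFactors = FALSE)
}

#' Write a QC report as TSV and JSON
#'
#' @param report data frame from [qc_report()].
#' @param path_prefix files `<path_prefix>.tsv` and `<path_prefix>.json`
#'   are written.
#' @return The two paths, invisibly.
#' @export
write_qc_report <- function(report, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  .write_plain_tsv(report, tsv)
  jsonlite::write_json(stats::setNames(as.list(report$value), report$metric),
                       json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(tsv, json))
}
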