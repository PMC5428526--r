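#' Read a count matrix with annotations
#'
#' Reads a gene-by-cell count matrix either from a MatrixMarket triplet
#' directory (as written by [write_dataset()]: `counts.mtx` plus sibling
#' `genes.tsv` and `cells.tsv` name/annotation files, optionally
#' `meta.json`) or from a dense TSV whose first column holds gene ids and
#' whose header row holds cell ids. Gene and cell order is preserved from
#' the file. Entries must be non-negative integers; violations are rejected
#' with the offending coordinate named.
#'
#' @param path directory (for `mtx_triplet`) or file (for `tsv_dense`).
#' @param format `"mtx_triplet"` or `"tsv_dense"`.
#' @param protocol protocol tag used when the source carries none.
#' @param provenance provenance string; defaults to the path.
#' @return An [ExpressionDataset].
#' @export
read_count_matrix <- function(path, format = c("mtx_triplet", "tsv_dense"),
                              protocol = "full_length", provenance = path) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    .read_mtx_triplet(path, protocol, provenance)
  } else {
    .read_tsv_dense(path, protocol, provenance)
  }
}

.read_mtx_triplet <- function(dir, protocol, provenance) {
  mtx <- file.path(dir, "counts.mtx")
  gfile <- file.path(dir, "genes.tsv")
  cfile <- file.path(dir, "cells.tsv")
  for (f in c(mtx, gfile, cfile))
    if (!file.exists(f)) stop("missing file: ", f)
  m <- Matrix::readMM(mtx)
  trip <- Matrix::summary(m)
  bad <- which(trip$x < 0 | trip$x != round(trip$x))
  if (length(bad) > 0)
    stop("non-integer or negative count ", trip$x[bad[1]],
         " at gene ", trip$i[bad[1]], ", cell ", trip$j[bad[1]])
  genes <- .read_name_table(gfile, "gene_id")
  cells <- .read_name_table(cfile, "cell_id")
  if (nrow(m) != nrow(genes))
    stop("matrix declares ", nrow(m), " rows but ", gfile, " lists ",
         nrow(genes), " genes")
  if (ncol(m) != nrow(cells))
    stop("matrix declares ", ncol(m), " columns but ", cfile, " lists ",
         nrow(cells), " cells")
  meta <- file.path(dir, "meta.json")
  if (file.exists(meta)) {
    info <- jsonlite::read_json(meta)
    if (!is.null(info$protocol)) protocol <- info$protocol
    if (!is.null(info$provenance)) provenance <- info$provenance
  }
  counts <- as.matrix(m)
  storage.mode(counts) <- "integer"
  ExpressionDataset(counts, genes, cells, protocol = protocol,
                    provenance = provenance)
}

# Annotation TSV with a header line, or a bare one-name-per-line file.
.read_name_table <- function(path, id_col) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, id_col)) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    out <- data.frame(readLines(path), stringsAsFactors = FALSE)
    names(out) <- id_col
    out
  }
}

.read_tsv_dense <- function(path, protocol, provenance) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric entries in ", path)
  bad <- which(vals < 0 | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-integer or negative count ", vals[bad[1, 1], bad[1, 2]],
         " at gene ", gene_ids[bad[1, 1]], ", cell ",
         colnames(vals)[bad[1, 2]])
  storage.mode(vals) <- "integer"
  rownames(vals) <- gene_ids
  ExpressionDataset(vals, gene_ids, colnames(vals), protocol = protocol,
                    provenance = provenance)
}

#' Write a dataset as MatrixMarket triplet plus annotation tables
#'
#' Emits `counts.mtx` (coordinate format, integer field), `genes.tsv`,
#' `cells.tsv` and `meta.json` into `out_dir`. [read_count_matrix()] on the
#' output round-trips counts and annotations exactly.
#'
#' @param dataset an [ExpressionDataset].
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  validate_dataset(dataset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  sp <- Matrix::Matrix(dataset$counts, sparse = TRUE)
  trip <- Matrix::summary(sp)
  trip <- trip[trip$x != 0, , drop = FALSE]
  # Matrix::writeMM types count matrices as 'real'; counts are integers, so
  # the integer-field coordinate header is written directly (readMM accepts
  # both).
  con <- file(file.path(out_dir, "counts.mtx"), "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(dataset$counts),
                       ncol(dataset$counts), nrow(trip))), con)
  if (nrow(trip) > 0)
    writeLines(sprintf("%d %d %d", trip$i, trip$j, as.integer(trip$x)), con)
  .write_plain_tsv(dataset$genes, file.path(out_dir, "genes.tsv"))
  .write_plain_tsv(dataset$cells, file.path(out_dir, "cells.tsv"))
  jsonlite::write_json(
    list(protocol = dataset$protocol, provenance = dataset$provenance,
         n_genes = nrow(dataset$counts), n_cells = ncol(dataset$counts)),
    file.path(out_dir, "meta.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

.write_plain_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Union-exon gene lengths from a GTF annotation
#'
#' Computes, per gene, the total number of genomic bases covered by at
#' least one exon of any transcript: overlapping or duplicated exon
#' intervals are merged across transcripts (strand ignored) and the merged
#' widths summed. GTF coordinates are 1-based inclusive, so an exon
#' `[a, b]` spans `b - a + 1` bases. This reproduces the per-gene `Length`
#' that exon-union read counters report.
#'
#' @param gtf_path path to a GTF file with `exon` features carrying
#'   `gene_id` attributes.
#' @return Named integer vector, gene id to union-exon length in bp. Genes
#'   without exon features are absent.
#' @export
union_exon_lengths <- function(gtf_path) {
  gr <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e)
      stop("failed to parse GTF '", gtf_path,
           "' (malformed record, e.g. exon end < start): ",
           conditionMessage(e)))
  ex <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(ex) == 0) return(stats::setNames(integer(0), character(0)))
  if (is.null(ex$gene_id) || anyNA(ex$gene_id))
    stop("exon feature without gene_id attribute in ", gtf_path)
  merged <- GenomicRanges::reduce(
    S4Vectors::split(GenomicRanges::granges(ex), ex$gene_id),
    ignore.strand = TRUE)
  lens <- vapply(GenomicRanges::width(merged), sum, integer(1))
  lens[order(names(lens))]
}

#' Default gene classification patterns
#'
#' Prefix rules for recognizing spike-in, mitochondrial and ribosomal
#' genes: ids starting `ERCC-` are spike-ins; symbols with an `mt-`/`MT-`
#' prefix are mitochondrial; symbols with an `Rps`/`Rpl`/`RPS`/`RPL`
#' prefix are ribosomal. Precedence is spikein > mito > ribo.
#'
#' @return Named list of regular expressions (`spikein_id`, `mito_symbol`,
#'   `ribo_symbol`).
#' @export
default_class_patterns <- function() {
  list(spikein_id = "^ERCC-",
       mito_symbol = "^(mt-|MT-)",
       ribo_symbol = "^(Rps|Rpl|RPS|RPL)")
}

#' Assign gene classes by identifier and symbol patterns
#'
#' @param genes gene annotation data frame with `gene_id` and `symbol`.
#' @param patterns rule set as returned by [default_class_patterns()];
#'   override individual entries to change recognition.
#' @return The gene table with `gene_class` filled; unmatched genes stay
#'   `ordinary`.
#' @export
classify_genes <- function(genes, patterns = default_class_patterns()) {
  genes <- .complete_gene_table(as.data.frame(genes))
  cls <- rep("ordinary", nrow(genes))
  cls[grepl(patterns$ribo_symbol, genes$symbol)] <- "ribo"
  cls[grepl(patterns$mito_symbol, genes$symbol)] <- "mito"
  cls[grepl(patterns$spikein_id, genes$gene_id)] <- "spikein"
  genes$gene_class <- cls
  genes
}
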