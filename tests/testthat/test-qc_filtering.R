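test_that("cell metrics follow their definitions", {
  counts <- cbind(c(0L, 0L, 3L, 1L), c(2L, 0L, 0L, 8L), c(0L, 0L, 0L, 0L))
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "ERCC-1"),
                      gene_class = c("ordinary", "ordinary", "ordinary",
                                     "spikein"))
  ds <- make_dataset(counts, genes)
  m <- compute_cell_metrics(ds)
  expect_equal(m$dropout_fraction, c(0.5, 0.5, 1.0))
  expect_equal(m$library_size, c(4, 10, 0))
  expect_equal(m$spikein_fraction, c(1 / 4, 0.8, 0))
})

test_that("cell filter keeps threshold-equal cells and applies all predicates", {
  # dropout exactly at the cap is retained ("greater than" removes)
  counts <- matrix(0L, 5, 2)
  counts[1, 1] <- 10L            # cell 1: dropout 4/5 = 0.80
  counts[, 2] <- 1L              # cell 2: dropout 0
  ds <- make_dataset(counts)
  kept <- filter_cells(ds, qc_thresholds(max_dropout = 0.80))
  expect_equal(ncol(kept$counts), 2)

  # library-size floor: of libraries 4, 600000, 2 only the second survives
  counts2 <- rbind(c(2L, 300000L, 1L), c(2L, 300000L, 1L))
  ds2 <- make_dataset(counts2)
  kept2 <- filter_cells(ds2, qc_thresholds(min_library_size = 5e5))
  expect_equal(kept2$cells$cell_id, ds2$cells$cell_id[2])

  # extreme thresholds are the identity filter
  ident <- filter_cells(ds2, qc_thresholds())
  expect_identical(ident$counts, ds2$counts)

  # removing every cell warns but yields a valid empty dataset
  expect_warning(none <- filter_cells(ds2, qc_thresholds(min_library_size = 1e9)),
                 "removed every cell")
  expect_equal(ncol(none$counts), 0)
})

test_that("spike-in fraction cap is applied only when set", {
  counts <- rbind(c(2L, 9L), c(8L, 1L))
  genes <- data.frame(gene_id = c("g1", "ERCC-1"),
                      gene_class = c("ordinary", "spikein"))
  ds <- make_dataset(counts, genes)
  # spike fractions 0.8 and 0.1
  kept <- filter_cells(ds, qc_thresholds(max_spikein_fraction = 0.2))
  expect_equal(kept$cells$cell_id, ds$cells$cell_id[2])
  all_kept <- filter_cells(ds, qc_thresholds())
  expect_equal(ncol(all_kept$counts), 2)
})

test_that("per-dataset presets carry the published thresholds", {
  k <- qc_preset("kolodziejczyk")
  expect_equal(c(k$max_dropout, k$min_library_size), c(0.80, 5e5))
  t <- qc_preset("tung")
  expect_equal(c(t$max_dropout, t$min_library_size, t$max_spikein_fraction),
               c(0.70, 3e4, 0.03))
  expect_equal(qc_preset("ziegenhain")$max_dropout, 1)
  expect_error(qc_preset("nonesuch"), "unknown QC preset")
})

test_that("gene filter enforces the 90%-zeroes rule at the boundary", {
  counts <- matrix(0L, 2, 100)
  counts[1, 1:9] <- 1L     # 91 zeros of 100 -> removed
  counts[2, 1:10] <- 1L    # 90 zeros of 100 -> retained
  genes <- data.frame(gene_id = c("gA", "gB"), length_bp = 1000L)
  ds <- make_dataset(counts, genes)
  kept <- filter_genes(ds)
  expect_equal(kept$genes$gene_id, "gB")
})

test_that("the 6-gene toy retains exactly the two hand-enumerated survivors", {
  ds <- toy_qc_dataset()
  kept <- filter_genes(ds)
  expect_equal(kept$genes$gene_id, c("g1", "g2"))
  log <- attr(kept, "filter_log")
  expect_equal(log$genes_removed_class, 2)      # mito + ribo
  expect_equal(log$genes_removed_spikein, 1)
  expect_equal(log$genes_removed_no_length, 1)
  expect_equal(log$genes_removed_zero_fraction, 0)
  # spike-in totals preserved on the cell table
  expect_equal(kept$cells$spikein_counts, c(2, 2, 2, 0, 0))
})

test_that("ribosomal genes are removed regardless of zero fraction", {
  counts <- rbind(rep(5L, 4), rep(7L, 4))
  genes <- classify_genes(data.frame(gene_id = c("r1", "o1"),
                                     symbol = c("Rpl3", "Actb"),
                                     length_bp = 1000L))
  kept <- filter_genes(make_dataset(counts, genes))
  expect_equal(kept$genes$gene_id, "o1")
})

test_that("qc_report counts retained and removed entities", {
  ds <- toy_qc_dataset()
  after <- filter_genes(filter_cells(ds, qc_thresholds()))
  rep <- qc_report(ds, after)
  val <- function(m) rep$value[rep$metric == m]
  expect_equal(val("genes_before"), 6)
  expect_equal(val("genes_after"), 2)
  expect_equal(val("cells_removed"), 0)
  expect_equal(val("genes_removed_class"), 2)

  ident <- qc_report(ds, ds)
  expect_true(all(ident$value[grepl("removed", ident$metric)] == 0))

  paths <- write_qc_report(rep, tempfile())
  expect_true(all(file.exists(paths)))
  back <- jsonlite::read_json(paths[2])
  expect_equal(back$genes_after, 2)
})

test_that("filtering is idempotent and preserves survivor order", {
  set.seed(11)
  counts <- matrix(rpois(400, 0.6), 40, 10)
  genes <- classify_genes(data.frame(
    gene_id = sprintf("g%02d", 1:40),
    symbol = c(sprintf("Gene%d", 1:36), "mt-X", "Rpl9", "ERCC-1", "Short"),
    length_bp = c(sample(200:9000, 39, replace = TRUE), NA),
    curated = c(rep(TRUE, 38), TRUE, TRUE)))
  genes$gene_id[39] <- "ERCC-1"
  ds <- make_dataset(counts, genes)
  thr <- qc_thresholds(max_dropout = 0.95, min_library_size = 3)
  once <- filter_genes(filter_cells(ds, thr))
  twice <- filter_genes(filter_cells(once, thr))
  expect_identical(once$counts, twice$counts)
  expect_identical(once$genes$gene_id, twice$genes$gene_id)
  # survivors appear in original order
  expect_true(!is.unsorted(match(once$genes$gene_id, ds$genes$gene_id)))
  expect_true(!is.unsorted(match(once$cells$cell_id, ds$cells$cell_id)))
})

test_that("cell filter equals brute-force predicate evaluation", {
  set.seed(12)
  counts <- matrix(rpois(600, 1.2), 20, 30)
  genes <- data.frame(gene_id = sprintf("g%d", 1:20),
                      gene_class = c(rep("ordinary", 18), "spikein", "spikein"))
  genes$gene_id[19:20] <- c("ERCC-1", "ERCC-2")
  ds <- make_dataset(counts, genes)
  thr <- qc_thresholds(max_dropout = 0.4, min_library_size = 20,
                       max_spikein_fraction = 0.15)
  kept <- filter_cells(ds, thr)$cells$cell_id
  expected <- character(0)
  for (j in seq_len(ncol(counts))) {
    col <- counts[, j]
    drop <- mean(col == 0)
    lib <- sum(col)
    spike <- if (lib > 0) sum(col[19:20]) / lib else 0
    if (drop <= 0.4 && lib >= 20 && spike <= 0.15)
      expected <- c(expected, ds$cells$cell_id[j])
  }
  expect_equal(kept, expected)
})

test_that("batch spike-in summary aggregates per batch", {
  counts <- rbind(c(1L, 1L, 8L, 8L), c(9L, 9L, 2L, 2L))
  genes <- data.frame(gene_id = c("g1", "ERCC-1"),
                      gene_class = c("ordinary", "spikein"))
  cells <- data.frame(cell_id = sprintf("c%d", 1:4),
                      batch = c("p1", "p1", "p2", "p2"))
  ds <- make_dataset(counts, genes, cells)
  s <- batch_spikein_summary(ds)
  expect_equal(s$median_spikein_fraction[s$batch == "p1"], 0.9)
  expect_equal(s$median_spikein_fraction[s$batch == "p2"], 0.2)
})
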