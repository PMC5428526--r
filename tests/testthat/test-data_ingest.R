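test_that("dense TSV counts are read in file order", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tc1\tc2", "gA\t1\t0", "gB\t2\t3"), path)
  ds <- read_count_matrix(path, "tsv_dense")
  expect_equal(unname(ds$counts), matrix(c(1L, 2L, 0L, 3L), 2))
  expect_equal(ds$genes$gene_id, c("gA", "gB"))
  expect_equal(ds$cells$cell_id, c("c1", "c2"))
})

test_that("sparse triplet expands to the declared dense matrix", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 1", "2 1 5"), file.path(dir, "counts.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "cells.tsv"))
  ds <- read_count_matrix(dir, "mtx_triplet")
  expect_equal(unname(ds$counts), matrix(c(0L, 5L, 0L, 0L, 0L, 0L), 3))
})

test_that("non-integer and negative entries are rejected with coordinates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tc1", "gA\t1.5"), path)
  expect_error(read_count_matrix(path, "tsv_dense"), "non-integer.*gA.*c1")
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tc1", "gA\t-2"), path2)
  expect_error(read_count_matrix(path2, "tsv_dense"), "negative")
})

test_that("name-file dimension mismatch is an error", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 1", "2 1 5"), file.path(dir, "counts.mtx"))
  writeLines(c("g1", "g2"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "cells.tsv"))
  expect_error(read_count_matrix(dir, "mtx_triplet"), "3 rows but .* 2 genes")
})

test_that("write_dataset round-trips counts and annotations exactly", {
  set.seed(42)
  counts <- matrix(rpois(50, 2), 10, 5)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:10),
                      symbol = sprintf("Sym%d", 1:10),
                      length_bp = c(NA, sample(200:5000, 9)),
                      curated = rep(c(TRUE, FALSE), 5))
  ds <- make_dataset(counts, classify_genes(genes), protocol = "umi")
  dir <- tempfile()
  write_dataset(ds, dir)
  rt <- read_count_matrix(dir, "mtx_triplet")
  expect_identical(rt$counts, ds$counts)
  expect_identical(rt$genes, ds$genes)
  expect_identical(rt$cells, ds$cells)
  expect_identical(rt$protocol, "umi")
})

test_that("MTX header declares the nonzero count; empty datasets are valid", {
  counts <- matrix(0L, 10, 3)
  counts[cbind(c(1, 4, 4, 9), c(1, 2, 3, 1))] <- c(2L, 1L, 7L, 4L)
  ds <- make_dataset(counts)
  dir <- tempfile()
  write_dataset(ds, dir)
  header <- readLines(file.path(dir, "counts.mtx"), n = 2)
  expect_equal(header[2], "10 3 4")

  empty <- make_dataset(matrix(0L, 0, 3),
                        genes = data.frame(gene_id = character(0)),
                        cells = sprintf("c%d", 1:3))
  dir2 <- tempfile()
  write_dataset(empty, dir2)
  rt <- read_count_matrix(dir2, "mtx_triplet")
  expect_equal(dim(rt), c(0L, 3L))
})

test_that("union-exon lengths merge overlapping and duplicated exons", {
  p1 <- write_gtf(list(list(start = 1, end = 100, gene = "gA"),
                       list(start = 51, end = 150, gene = "gA", tx = "gA.t2")))
  expect_equal(union_exon_lengths(p1), c(gA = 150L))

  p2 <- write_gtf(list(list(start = 10, end = 10, gene = "gB")))
  expect_equal(union_exon_lengths(p2), c(gB = 1L))

  p3 <- write_gtf(list(list(start = 1, end = 100, gene = "gC"),
                       list(start = 201, end = 300, gene = "gC", tx = "gC.t2")))
  expect_equal(union_exon_lengths(p3), c(gC = 200L))
})

test_that("union-exon lengths are invariant to exon order and duplication", {
  rows <- list(list(start = 500, end = 900, gene = "gD"),
               list(start = 100, end = 600, gene = "gD", tx = "gD.t2"),
               list(start = 2000, end = 2100, gene = "gD", tx = "gD.t3"))
  base <- union_exon_lengths(write_gtf(rows))
  shuffled <- union_exon_lengths(write_gtf(rev(rows)))
  duplicated <- union_exon_lengths(write_gtf(c(rows, rows)))
  expect_equal(shuffled, base)
  expect_equal(duplicated, base)
})

test_that("union-exon lengths match per-base occupancy on random genes", {
  set.seed(7)
  for (rep in 1:5) {
    n_exons <- sample(1:6, 1)
    starts <- sample(1:9000, n_exons)
    ends <- pmin(starts + sample(1:800, n_exons, replace = TRUE), 10000)
    rows <- lapply(seq_len(n_exons), function(i)
      list(start = starts[i], end = ends[i], gene = "gR",
           tx = sprintf("gR.t%d", i)))
    occupied <- logical(10000)
    for (i in seq_len(n_exons)) occupied[starts[i]:ends[i]] <- TRUE
    expect_equal(union_exon_lengths(write_gtf(rows)),
                 c(gR = sum(occupied)))
  }
})

test_that("malformed exon coordinates are an error", {
  path <- tempfile(fileext = ".gtf")
  writeLines("chr1\ttest\texon\t100\t50\t.\t+\t.\tgene_id \"gX\"; transcript_id \"gX.t1\";",
             path)
  expect_error(union_exon_lengths(path))
})

test_that("gene classes follow prefix rules with spikein precedence", {
  genes <- data.frame(
    gene_id = c("ERCC-00130", "g2", "g3", "g4", "ERCC-00002"),
    symbol = c("ERCC-00130", "mt-Nd1", "Rpl13a", "Actb", "mt-Fake"))
  out <- classify_genes(genes)
  expect_equal(out$gene_class,
               c("spikein", "mito", "ribo", "ordinary", "spikein"))
  # uppercase variants and custom overrides
  out2 <- classify_genes(data.frame(gene_id = c("a", "b"),
                                    symbol = c("MT-ND1", "RPS4X")))
  expect_equal(out2$gene_class, c("mito", "ribo"))
  custom <- default_class_patterns()
  custom$spikein_id <- "^SIRV-"
  out3 <- classify_genes(data.frame(gene_id = "SIRV-1", symbol = "SIRV-1"),
                         custom)
  expect_equal(out3$gene_class, "spikein")
})

test_that("dataset invariants are enforced", {
  expect_error(make_dataset(matrix(-1L, 1, 1)), "negative")
  genes <- data.frame(gene_id = "g1", gene_class = "plasmid")
  expect_error(ExpressionDataset(matrix(0L, 1, 1), genes), "gene_class")
  cells <- data.frame(cell_id = c("c1", "c1"))
  expect_error(ExpressionDataset(matrix(0L, 1, 2), "g1", cells), "duplicate")
})
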