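# Fixtures built in code: small datasets with hand-checkable structure.

make_dataset <- function(counts, genes = NULL, cells = NULL,
                         protocol = "full_length") {
  storage.mode(counts) <- "integer"
  ExpressionDataset(counts, genes, cells, protocol = protocol)
}

# 6-gene x 5-cell QC toy. Under the default gene policy (zero-fraction cap
# 0.90, mito/ribo excluded, curated id and length required, spike-ins
# removed from the analysis matrix) exactly Actb and Gapdh survive:
#   g1 Actb   ordinary len 2000  zeros 1/5
#   g2 Gapdh  ordinary len 1500  zeros 3/5
#   g3 mt-Nd1 mito     len  900  (class-excluded)
#   g4 Rpl13a ribo     len  700  (class-excluded)
#   g5 ERCC-00130 spikein len 1023 (spike-in, removed from matrix)
#   g6 Novel1 ordinary len NA    (missing length)
toy_qc_dataset <- function() {
  counts <- rbind(
    c(5L, 0L, 3L, 2L, 1L),
    c(1L, 1L, 0L, 0L, 0L),
    c(10L, 8L, 5L, 4L, 2L),
    c(3L, 3L, 3L, 3L, 3L),
    c(2L, 2L, 2L, 0L, 0L),
    c(4L, 0L, 0L, 0L, 0L))
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    symbol = c("Actb", "Gapdh", "mt-Nd1", "Rpl13a", "ERCC-00130", "Novel1"),
    length_bp = c(2000L, 1500L, 900L, 700L, 1023L, NA),
    curated = TRUE, stringsAsFactors = FALSE)
  genes$gene_id[5] <- "ERCC-00130"
  genes <- classify_genes(genes)
  ExpressionDataset(counts, genes, sprintf("cell%d", 1:5),
                    protocol = "full_length")
}

# Dataset in which exactly the genes in `detected` carry nonzero counts in
# >= 10% of the cells (10 cells -> threshold 1 nonzero cell; non-detected
# genes are all zero).
dataset_with_detected <- function(all_genes, detected, id = "d1",
                                  protocol = "full_length") {
  counts <- matrix(0L, length(all_genes), 10)
  counts[match(detected, all_genes), ] <- 1L
  genes <- data.frame(gene_id = all_genes,
                      length_bp = 1000L, stringsAsFactors = FALSE)
  cells <- data.frame(cell_id = sprintf("%s_c%d", id, 1:10),
                      dataset_id = id, stringsAsFactors = FALSE)
  ExpressionDataset(counts, genes, cells, protocol = protocol)
}

write_gtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  lines <- vapply(rows, function(r)
    sprintf("chr1\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            r$start, r$end, if (is.null(r$strand)) "+" else r$strand,
            r$gene, if (is.null(r$tx)) paste0(r$gene, ".t1") else r$tx),
    character(1))
  writeLines(lines, path)
  path
}

write_gmt_file <- function(categories, path = tempfile(fileext = ".gmt")) {
  writeLines(vapply(categories, function(cat)
    paste(c(cat$category_id, cat$name, cat$members), collapse = "\t"),
    character(1)), path)
  path
}

# Brute-force hypergeometric upper tail by enumerating all C(N, n) draws.
brute_hyper_upper <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Brute-force two-sided rank-sum p by enumerating all group assignments.
brute_wilcox_two_sided <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  nm <- n * length(y) / 2  # E[U] under the null
  assignments <- utils::combn(length(pooled), n)
  stats <- apply(assignments, 2, function(idx)
    sum(r[idx]) - n * (n + 1) / 2)
  mean(abs(stats - nm) >= abs(obs - nm) - 1e-9)
}

# All permutations of 1:n (small n only).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1))
    for (pos in seq_len(n))
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
  out
}

# Textbook Benjamini-Hochberg step-up.
bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
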