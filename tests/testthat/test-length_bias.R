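test_that("log CPM follows its closed form and scale invariances", {
  counts <- matrix(c(0L, 1L, 3L, 7L), 2)
  lc <- log_cpm(counts)
  expect_equal(lc[1, 1], 0)  # zero count -> log2(0 + 1)
  one <- matrix(1L, 1, 1)
  expect_equal(log_cpm(one)[1, 1], log2(1e6 + 1))
  # doubling every count in a cell leaves its log-CPM column unchanged
  doubled <- counts
  doubled[, 2] <- doubled[, 2] * 2L
  expect_equal(log_cpm(doubled)[, 2], lc[, 2])
  # zero library size names the cell
  bad <- matrix(c(1L, 0L), 1)
  colnames(bad) <- c("good", "empty")
  expect_error(log_cpm(bad), "empty")
})

test_that("RPKM unit cases and the length-1000 CPM identity hold", {
  counts <- matrix(10L, 1, 1)
  expect_equal(rpkm(counts, 1000, lib_size = 1e6)[1, 1], 10)
  expect_equal(rpkm(counts, 500, lib_size = 1e6)[1, 1], 20)
  set.seed(5)
  m <- matrix(rpois(40, 4), 4)
  cpm <- 2^log_cpm(m) - 1
  expect_equal(rpkm(m, rep(1000, 4)), cpm, tolerance = 1e-12)
  expect_error(rpkm(m, c(1000, NA, 1000, 1000)), "missing")
})

test_that("gene summaries match hand arithmetic on a 2x2 toy", {
  counts <- rbind(c(1L, 0L), c(9L, 10L))
  genes <- data.frame(gene_id = c("gA", "gB"), length_bp = c(500L, 2000L))
  ds <- make_dataset(counts, genes)
  s <- gene_summaries(ds, n_bins = 2)
  # libraries 10 and 10; CPM row A = (1e5, 0), row B = (9e5, 1e6)
  expect_equal(s$mean_log_cpm[1], (log2(1e5 + 1) + 0) / 2)
  expect_equal(s$mean_log_cpm[2], (log2(9e5 + 1) + log2(1e6 + 1)) / 2)
  expect_equal(s$dropout_rate, c(0.5, 0))
  # RPKM divides CPM by length/1000
  expect_equal(s$mean_log_rpkm[1], (log2(1e5 / 0.5 + 1) + 0) / 2)
  expect_equal(s$bin_id, c(1L, 2L))
})

test_that("dropout rate is the per-gene zero fraction", {
  counts <- rbind(c(0L, 0L, 3L, 0L), c(1L, 2L, 3L, 4L))
  ds <- make_dataset(counts,
                     data.frame(gene_id = c("a", "b"), length_bp = 1000L))
  s <- gene_summaries(ds, n_bins = 1)
  expect_equal(s$dropout_rate, c(0.75, 0))
})

test_that("spike-ins are excluded from the library-size denominator by default", {
  counts <- rbind(c(5L, 5L), c(5L, 5L))
  genes <- data.frame(gene_id = c("g1", "ERCC-1"),
                      length_bp = 1000L,
                      gene_class = c("ordinary", "spikein"))
  ds <- make_dataset(counts, genes)
  s <- gene_summaries(ds, n_bins = 1)
  expect_equal(s$mean_log_cpm[1], log2(1e6 + 1))  # lib = 5, not 10
  s2 <- gene_summaries(ds, n_bins = 1, exclude_spikeins_from_libsize = FALSE)
  expect_equal(s2$mean_log_cpm[1], log2(5e5 + 1))
})

test_that("length bins are balanced, ordered and deterministic", {
  # 20 genes, 10 bins: exactly 2 each
  set.seed(3)
  len20 <- sample(200:10000, 20)
  b <- assign_length_bins(len20, 10)
  expect_true(all(table(b) == 2))
  # 1003 genes: seven bins of 100, the last three of 101
  len <- sample(200:100000, 1003, replace = TRUE)
  b2 <- assign_length_bins(len, 10)
  expect_equal(as.vector(table(b2)), c(rep(100L, 7), rep(101L, 3)))
  # bin 1 holds the shortest genes; concatenating bins recovers sorted order
  expect_true(max(len[b2 == 1]) <= min(len[b2 == 10]))
  ids <- sprintf("g%04d", seq_along(len))
  ord <- order(len, ids)
  expect_equal(b2[ord], rep(1:10, c(rep(100, 7), rep(101, 3))))
  # ties broken by gene id, reproducibly
  same <- rep(1000L, 10)
  names(same) <- sprintf("g%02d", 10:1)
  expect_identical(assign_length_bins(same, 5), assign_length_bins(same, 5))
  expect_equal(assign_length_bins(same, 5)[10], 1L)  # "g01" sorts first
  expect_error(assign_length_bins(same, 0), "n_bins")
  expect_error(assign_length_bins(same, 11), "exceeds")
})

test_that("bin summaries report interpolated quartiles", {
  s <- data.frame(gene_id = sprintf("g%d", 1:6),
                  length_bp = c(1, 2, 3, 10, 20, 30),
                  mean_log_cpm = c(1, 2, 3, 5, 5, 5),
                  dropout_rate = c(0.1, 0.2, 0.3, 0, 0, 0),
                  mean_log_rpkm = c(1, 2, 3, 5, 5, 5),
                  bin_id = c(1L, 1L, 1L, 2L, 2L, 2L))
  b <- bin_summaries(s)
  expect_equal(b$cpm_median, c(2, 5))
  expect_equal(b$cpm_q75[2] - b$cpm_q25[2], 0)  # constant bin, zero IQR
  expect_equal(b$n_genes, c(3L, 3L))
  expect_equal(b$length_max, c(3, 30))
})

test_that("spearman trend is exact on monotone and anti-monotone inputs", {
  x <- c(100, 200, 300, 400)
  up <- spearman_trend(x, x * 3)
  expect_equal(unname(up["rho"]), 1)
  down <- spearman_trend(x, rev(x))
  expect_equal(unname(down["rho"]), -1)
  expect_true(is.na(spearman_trend(x, rep(1, 4))["rho"]))
})

test_that("spearman matches the exact rank formula over permutations", {
  x <- c(3.2, 1.1, 5.6, 2.2, 9.9)
  n <- length(x)
  perms <- matrix(unlist(combinat_perms(n)), nrow = n)
  for (j in seq_len(ncol(perms))) {
    y <- perms[, j]
    d <- rank(x) - rank(y)
    exact <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
    expect_equal(unname(spearman_trend(x, y)["rho"]), exact)
  }
})

test_that("spearman is near zero for length-independent statistics", {
  set.seed(21)
  len <- rlnorm(5000, log(2500), 1)
  stat <- sample(rnorm(5000))
  expect_lt(abs(spearman_trend(len, stat)["rho"]), 0.1)
})

test_that("length_bias_statistics quantifies the simulated trends", {
  s <- data.frame(gene_id = sprintf("g%d", 1:50),
                  length_bp = 1:50,
                  mean_log_cpm = (1:50) / 10,
                  dropout_rate = seq(1, 0, length.out = 50),
                  mean_log_rpkm = rnorm(50),
                  bin_id = 1L)
  out <- length_bias_statistics(s)
  expect_equal(out$rho_count, 1)
  expect_equal(out$rho_dropout, -1)
  expect_lt(out$p_count, 1e-10)
  expect_error(length_bias_statistics(s[1:5, ]), "at least 10")
})
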