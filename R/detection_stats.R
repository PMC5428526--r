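#' Read gene-set categories from a GMT file
#'
#' One category per tab-separated line: id, name/description, then member
#' gene ids. Duplicate members within a category are dropped.
#'
#' @param path GMT file.
#' @return Named list; each element is `list(category_id, name, members)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields: ", l)
    list(category_id = f[1], name = f[2], members = unique(f[-(1:2)]))
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "category_id"))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks are used for ties. The statistic is the Mann-Whitney U of `x`.
#' The p-value is exact (by the rank-sum distribution) when the samples
#' are untied and `n + m <= 16`, otherwise the normal approximation with
#' tie correction and continuity correction is used. Two samples whose
#' pooled values are all identical give p = 1.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (`x` relative
#'   to `y`).
#' @return List with `statistic`, `p_value` and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n + m <= 16) {
    p <- switch(alternative,
      less = stats::pwilcox(W, n, m),
      greater = stats::pwilcox(W - 1, n, m, lower.tail = FALSE),
      two_sided = if (W == n * m / 2) 1 else
        min(1, 2 * min(stats::pwilcox(W, n, m),
                       stats::pwilcox(W - 1, n, m, lower.tail = FALSE))))
    return(list(statistic = W, p_value = p, method = "exact"))
  }
  nties <- table(r)
  z <- W - n * m / 2
  sigma2 <- (n * m / 12) *
    ((n + m + 1) - sum(nties^3 - nties) / ((n + m) * (n + m - 1)))
  if (sigma2 <= 0)
    return(list(statistic = W, p_value = 1, method = "normal_approx"))
  corr <- switch(alternative,
                 two_sided = sign(z) * 0.5, greater = 0.5, less = -0.5)
  zc <- (z - corr) / sqrt(sigma2)
  p <- switch(alternative,
              less = stats::pnorm(zc),
              greater = stats::pnorm(zc, lower.tail = FALSE),
              two_sided = min(1, 2 * min(stats::pnorm(zc),
                                         stats::pnorm(zc, lower.tail = FALSE))))
  list(statistic = W, p_value = p, method = "normal_approx")
}

#' Hypergeometric upper-tail test
#'
#' Probability of drawing at least `k` category members when `n` genes are
#' drawn without replacement from a universe of `N` genes containing `K`
#' category members:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n)`, evaluated
#' stably (log-space) via the hypergeometric distribution function.
#'
#' @param k observed overlap.
#' @param K category size within the universe.
#' @param n drawn set size.
#' @param N universe size.
#' @return Upper-tail p-value in (0, 1].
#' @export
hypergeometric_test <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals != round(vals)) || any(vals < 0))
    stop("arguments must be non-negative integers")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n)) stop("k must not exceed min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of a gene set against categories
#'
#' Categories are intersected with the universe before testing; every
#' category retaining at least one universe member receives one
#' upper-tail hypergeometric test, Benjamini-Hochberg adjusted across the
#' tested categories. When lengths are supplied, each category is assigned
#' the median length of its universe members with known lengths.
#'
#' @param gene_set character vector, subset of `universe`.
#' @param categories list from [read_gmt()].
#' @param universe character vector of testable gene ids.
#' @param fdr_alpha significance level on the adjusted p-values.
#' @param lengths optional named vector of gene lengths (bp).
#' @return data frame with one row per tested category: `category_id`,
#'   `name`, `n_category_in_universe`, `n_overlap`, `p_value`, `fdr`,
#'   `significant`, `median_member_length`.
#' @export
enrich <- function(gene_set, categories, universe, fdr_alpha = 0.05,
                   lengths = NULL) {
  if (length(universe) == 0) stop("universe is empty")
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  rows <- lapply(categories, function(cat) {
    members <- intersect(cat$members, universe)
    if (length(members) == 0) return(NULL)
    k <- length(intersect(members, gene_set))
    med <- if (is.null(lengths)) NA_real_ else
      stats::median(lengths[intersect(members, names(lengths))], na.rm = TRUE)
    data.frame(category_id = cat$category_id, name = cat$name,
               n_category_in_universe = length(members), n_overlap = k,
               p_value = hypergeometric_test(k, length(members),
                                             length(gene_set),
                                             length(universe)),
               median_member_length = med, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(category_id = character(0), name = character(0),
                      n_category_in_universe = integer(0),
                      n_overlap = integer(0), p_value = numeric(0),
                      fdr = numeric(0), significant = logical(0),
                      median_member_length = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr <= fdr_alpha
  out[, c("category_id", "name", "n_category_in_universe", "n_overlap",
          "p_value", "fdr", "significant", "median_member_length")]
}

#' Variance-ratio (F) test on category median lengths
#'
#' Compares the spread of per-category median gene lengths between two
#' groups of enriched categories: `F = var(a) / var(b)` with sample
#' variances, and a two-sided p-value
#' `2 * min(P[F_{df_a, df_b} >= F], P[<= F])`. Set `log_scale = TRUE` to
#' compare spreads of log lengths instead of raw lengths.
#'
#' @param lengths_a,lengths_b numeric vectors of per-category median
#'   lengths (each of length >= 2).
#' @param log_scale compare on the natural-log scale.
#' @return List with `variance_ratio`, `df`, `p_value`.
#' @export
category_length_spread_test <- function(lengths_a, lengths_b,
                                        log_scale = FALSE) {
  if (length(lengths_a) < 2 || length(lengths_b) < 2)
    stop("each group needs at least 2 category lengths")
  if (log_scale) {
    if (any(lengths_a <= 0) || any(lengths_b <= 0))
      stop("log scale requires positive lengths")
    lengths_a <- log(lengths_a); lengths_b <- log(lengths_b)
  }
  va <- stats::var(lengths_a); vb <- stats::var(lengths_b)
  if (vb == 0) stop("zero variance in denominator group")
  f <- va / vb
  dfa <- length(lengths_a) - 1; dfb <- length(lengths_b) - 1
  p <- min(1, 2 * min(stats::pf(f, dfa, dfb),
                      stats::pf(f, dfa, dfb, lower.tail = FALSE)))
  list(variance_ratio = f, df = c(dfa, dfb), p_value = p)
}
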