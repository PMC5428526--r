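#' Protocol simulation design
#'
#' All truth-model and sampling parameters for the protocol simulator. The
#' mechanism: each gene has a baseline expression (expected captured
#' molecules per cell); molecule counts per cell are negative binomial
#' around expression x condition fold change x per-cell capture factor;
#' observed counts are Poisson reads around molecules x depth factor x
#' `(length / reference_length)^length_exponent`. With exponent 1 a
#' transcript twice as long yields twice the expected reads (fragmentation);
#' with exponent 0 counts are length-independent (molecule/UMI counting).
#' The depth factor is calibrated so the mean column sum matches
#' `depth_scale`.
#'
#' @param n_genes total genes including special classes.
#' @param n_cells cells.
#' @param protocol `"full_length"` or `"umi"`.
#' @param length_exponent read-count length exponent (default 1 for
#'   full-length, 0 for UMI).
#' @param length_log_mean,length_log_sd log-normal gene lengths in bp,
#'   clipped to `[200, 100000]`.
#' @param expr_log_mean,expr_log_sd log-normal baseline expression
#'   (expected captured molecules per cell).
#' @param capture_log_mean,capture_log_sd per-cell log-normal capture
#'   scaling (applies to endogenous genes, not spike-ins).
#' @param dispersion negative-binomial dispersion of molecule counts
#'   (variance `mu + dispersion * mu^2`).
#' @param reference_length length normalizer L0 in bp.
#' @param de_fraction fraction of ordinary genes with a condition effect.
#' @param de_log2fc_sd SD of the normal log2 fold-change effects.
#' @param n_spikeins,n_mito,n_ribo counts of special-class genes.
#' @param spikein_read_share expected share of reads from spike-ins.
#' @param depth_scale mean reads (or molecules) per cell.
#' @param conditions two condition labels, assigned alternately to cells.
#' @param dataset_id label recorded on the emitted cells.
#' @param seed integer; fixes the full output.
#' @return List of class `SimulationDesign`.
#' @export
simulation_design <- function(n_genes = 12000, n_cells = 200,
                              protocol = c("full_length", "umi"),
                              length_exponent = NULL,
                              length_log_mean = log(2500),
                              length_log_sd = 1.8,
                              expr_log_mean = log(4), expr_log_sd = 1.7,
                              capture_log_mean = 0, capture_log_sd = 0.7,
                              dispersion = 1.5, reference_length = 2500,
                              de_fraction = 0.1, de_log2fc_sd = 1,
                              n_spikeins = 92, n_mito = 13, n_ribo = 90,
                              spikein_read_share = 0.03,
                              depth_scale = NULL,
                              conditions = c("2i", "serum"),
                              dataset_id = NULL, seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(length_exponent))
    length_exponent <- if (protocol == "full_length") 1 else 0
  if (is.null(depth_scale))
    depth_scale <- (if (protocol == "full_length") 1e6 else 3e4) *
      n_genes / 12000
  if (is.null(dataset_id))
    dataset_id <- paste0("sim_", protocol)
  design <- structure(list(
    n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
    protocol = protocol, length_exponent = length_exponent,
    length_log_mean = length_log_mean, length_log_sd = length_log_sd,
    expr_log_mean = expr_log_mean, expr_log_sd = expr_log_sd,
    capture_log_mean = capture_log_mean, capture_log_sd = capture_log_sd,
    dispersion = dispersion, reference_length = reference_length,
    de_fraction = de_fraction, de_log2fc_sd = de_log2fc_sd,
    n_spikeins = as.integer(n_spikeins), n_mito = as.integer(n_mito),
    n_ribo = as.integer(n_ribo), spikein_read_share = spikein_read_share,
    depth_scale = depth_scale, conditions = conditions,
    dataset_id = dataset_id, seed = as.integer(seed)),
    class = "SimulationDesign")
  .validate_design(design)
  design
}

.validate_design <- function(d) {
  if (d$n_spikeins + d$n_mito + d$n_ribo > d$n_genes)
    stop("special-class gene counts exceed n_genes")
  stopifnot(d$n_genes > 0, d$n_cells > 0,
            d$length_log_sd > 0, d$expr_log_sd > 0, d$capture_log_sd >= 0,
            d$dispersion > 0, d$reference_length > 0, d$depth_scale > 0,
            d$de_fraction >= 0, d$de_fraction <= 1, d$de_log2fc_sd >= 0,
            d$spikein_read_share >= 0, d$spikein_read_share < 1,
            length(d$conditions) == 2)
  invisible(d)
}

#' mESC-like simulation design preset
#'
#' The default study conditions: a 12000-gene transcriptome with 92
#' spike-ins, two culture conditions, full-length depth 1e6 reads per cell
#' versus UMI depth 3e4 molecules per cell (echoing the deep full-length /
#' shallow UMI contrast of the published datasets). Depth is scaled
#' proportionally with `n_genes` so that scaled-down simulations keep the
#' same per-gene coverage and hence the same dropout structure.
#'
#' @param protocol `"full_length"` or `"umi"`.
#' @param n_genes,n_cells problem size (defaults 12000 genes, 200 cells).
#' @param seed integer seed.
#' @param ... further overrides passed to [simulation_design()].
#' @return A `SimulationDesign`.
#' @export
mesc_design <- function(protocol = c("full_length", "umi"), n_genes = 12000,
                        n_cells = 200, seed = 1L, ...) {
  protocol <- match.arg(protocol)
  simulation_design(n_genes = n_genes, n_cells = n_cells,
                    protocol = protocol, seed = seed, ...)
}

# Deterministic derived seeds: separate streams for gene truth, cell truth
# and count sampling so that re-seeding cannot couple the draws.
.derived_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 1299721) %% 2147483647)
}

#' Draw simulation ground truth
#'
#' Draws per-gene lengths (log-normal, clipped to 200-100000 bp), baseline
#' expressions (log-normal), gene classes with class-conforming symbols
#' (so that [classify_genes()] recognizes them), condition log2 fold
#' changes for a `de_fraction` of ordinary genes, and per-cell conditions
#' and capture factors. Spike-in genes get fixed expression across
#' conditions, scaled so they take `spikein_read_share` of the reads, and
#' short lengths typical of synthetic spike-in transcripts.
#'
#' @param design a [simulation_design()].
#' @return List of class `SimulationTruth` with elements `genes` (gene_id,
#'   symbol, length_bp, gene_class, curated, base_expr, log2_fc), `cells`
#'   (cell_id, condition, batch, capture) and `design`.
#' @export
draw_gene_truth <- function(design) {
  .validate_design(design)
  set.seed(.derived_seed(design$seed, 1))
  n <- design$n_genes
  n_ord <- n - design$n_spikeins - design$n_mito - design$n_ribo
  gene_class <- c(rep("ordinary", n_ord), rep("mito", design$n_mito),
                  rep("ribo", design$n_ribo), rep("spikein", design$n_spikeins))
  gene_id <- sprintf("G%05d", seq_len(n))
  symbol <- gene_id
  if (design$n_mito > 0) {
    i <- which(gene_class == "mito")
    symbol[i] <- sprintf("mt-Gene%d", seq_along(i))
  }
  if (design$n_ribo > 0) {
    i <- which(gene_class == "ribo")
    symbol[i] <- sprintf("%s%d", rep(c("Rpl", "Rps"), length.out = length(i)),
                         seq_along(i))
  }
  if (design$n_spikeins > 0) {
    i <- which(gene_class == "spikein")
    gene_id[i] <- sprintf("ERCC-%05d", seq_along(i))
    symbol[i] <- gene_id[i]
  }
  len <- pmin(pmax(round(stats::rlnorm(n, design$length_log_mean,
                                       design$length_log_sd)), 200), 100000)
  expr <- stats::rlnorm(n, design$expr_log_mean, design$expr_log_sd)
  sp <- gene_class == "spikein"
  if (any(sp)) {
    # synthetic spike-in transcripts are short (roughly 0.25-2 kb)
    len[sp] <- pmin(pmax(round(stats::rlnorm(sum(sp), log(800), 0.35)),
                         200), 2100)
    share <- design$spikein_read_share
    expr[sp] <- expr[sp] * (share / (1 - share)) *
      sum(expr[!sp]) / sum(expr[sp])
  }
  lfc <- numeric(n)
  ord_idx <- which(gene_class == "ordinary")
  n_de <- round(design$de_fraction * length(ord_idx))
  if (n_de > 0) {
    de_idx <- sample(ord_idx, n_de)
    lfc[de_idx] <- stats::rnorm(n_de, 0, design$de_log2fc_sd)
  }
  genes <- data.frame(gene_id = gene_id, symbol = symbol,
                      length_bp = as.integer(len), gene_class = gene_class,
                      curated = TRUE, base_expr = expr, log2_fc = lfc,
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, cells = draw_cell_truth(design),
                 design = design),
            class = "SimulationTruth")
}

#' Draw per-cell simulation truth
#'
#' Cells alternate between the two conditions and receive log-normal
#' capture factors. Used by [simulate_protocol_pair()] to give the second
#' protocol its own cells while sharing gene truth.
#'
#' @param design a [simulation_design()].
#' @return data frame with `cell_id`, `condition`, `batch`, `capture`.
#' @export
draw_cell_truth <- function(design) {
  set.seed(.derived_seed(design$seed, 2))
  data.frame(
    cell_id = sprintf("%s_C%04d", design$dataset_id, seq_len(design$n_cells)),
    condition = rep(design$conditions, length.out = design$n_cells),
    batch = "batch1",
    capture = stats::rlnorm(design$n_cells, design$capture_log_mean,
                            design$capture_log_sd),
    stringsAsFactors = FALSE)
}

#' Simulate observed counts from truth
#'
#' Molecules `M[g, c] ~ NegBin(mean = expr_g * 2^(lfc_g * cond_c) *
#' capture_c, dispersion)`; observed counts
#' `~ Poisson(M * d * (length_g / L0)^alpha)` with the global depth factor
#' `d` calibrated so that the mean column sum matches the design's
#' `depth_scale`. Spike-ins have condition- and capture-independent
#' molecule means. Dropout is emergent from sampling depth; there is no
#' explicit zero-inflation component.
#'
#' @param truth a [draw_gene_truth()] result whose gene count matches the
#'   design; its cells are used when their number matches `design$n_cells`.
#' @param design a [simulation_design()].
#' @return An [ExpressionDataset] tagged with the design's protocol. The
#'   molecule matrix and depth factor are attached as attributes
#'   `"molecules"` and `"depth_factor"`.
#' @export
simulate_counts <- function(truth, design) {
  stopifnot(inherits(truth, "SimulationTruth"))
  .validate_design(design)
  g <- truth$genes
  if (nrow(g) != design$n_genes)
    stop("truth has ", nrow(g), " genes but design expects ", design$n_genes)
  cells <- truth$cells
  if (nrow(cells) != design$n_cells)
    stop("truth has ", nrow(cells), " cells but design expects ",
         design$n_cells, "; redraw with draw_cell_truth()")
  set.seed(.derived_seed(design$seed, 3))
  cond01 <- as.numeric(cells$condition == design$conditions[2])
  sp <- g$gene_class == "spikein"
  mu <- (g$base_expr * 2^outer(g$log2_fc, cond01)) *
    rep(cells$capture, each = nrow(g))
  if (any(sp)) mu[sp, ] <- g$base_expr[sp]
  if (any(!is.finite(mu))) {
    bad <- which(!is.finite(mu), arr.ind = TRUE)[1, ]
    stop("non-finite molecule mean at gene ", g$gene_id[bad[1]],
         ", cell ", cells$cell_id[bad[2]])
  }
  M <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / design$dispersion),
              nrow = nrow(g))
  lenfac <- (g$length_bp / design$reference_length)^design$length_exponent
  d <- design$depth_scale / mean(colSums(M * lenfac))
  lambda <- M * lenfac * d
  if (any(!is.finite(lambda))) {
    bad <- which(!is.finite(lambda), arr.ind = TRUE)[1, ]
    stop("non-finite read mean at gene ", g$gene_id[bad[1]],
         ", cell ", cells$cell_id[bad[2]])
  }
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow = nrow(g))
  storage.mode(counts) <- "integer"
  cell_tab <- data.frame(cell_id = cells$cell_id,
                         dataset_id = design$dataset_id,
                         condition = cells$condition, batch = cells$batch,
                         stringsAsFactors = FALSE)
  out <- ExpressionDataset(
    counts,
    g[, c("gene_id", "symbol", "length_bp", "gene_class", "curated")],
    cell_tab, protocol = design$protocol,
    provenance = sprintf("simulated (%s, alpha=%g, depth=%g, seed=%d)",
                         design$protocol, design$length_exponent,
                         design$depth_scale, design$seed))
  attr(out, "molecules") <- M
  attr(out, "depth_factor") <- d
  out
}

#' Simulate a matched full-length / UMI protocol pair
#'
#' Both datasets share the gene-level truth (lengths, expressions, fold
#' changes); each gets its own cells. The full-length design uses length
#' exponent 1 and deep coverage, the UMI design exponent 0 and shallow
#' coverage, so detection differences between the two datasets are driven
#' by the length mechanism alone.
#'
#' @param truth gene truth from [draw_gene_truth()] (typically drawn from
#'   `design_fl`).
#' @param design_fl full-length design.
#' @param design_umi UMI design with the same `n_genes`.
#' @return List with `full_length` and `umi` [ExpressionDataset]s and the
#'   shared `truth`.
#' @export
simulate_protocol_pair <- function(truth, design_fl, design_umi) {
  stopifnot(inherits(truth, "SimulationTruth"))
  if (design_fl$n_genes != design_umi$n_genes ||
      nrow(truth$genes) != design_fl$n_genes)
    stop("designs and truth must agree on n_genes")
  if (design_fl$protocol != "full_length" || design_umi$protocol != "umi")
    stop("design_fl must be full_length and design_umi must be umi")
  truth_fl <- truth
  if (nrow(truth_fl$cells) != design_fl$n_cells)
    truth_fl$cells <- draw_cell_truth(design_fl)
  truth_umi <- truth
  truth_umi$cells <- draw_cell_truth(design_umi)
  list(full_length = simulate_counts(truth_fl, design_fl),
       umi = simulate_counts(truth_umi, design_umi),
       truth = truth)
}

#' Default mESC-like protocol pair
#'
#' Convenience wrapper building the shared truth and the matched pair at
#' the preset conditions. The UMI design derives a distinct seed from the
#' supplied one so that the two datasets have independent sampling noise.
#'
#' @param n_genes,n_cells problem size.
#' @param seed integer seed fixing the whole pair.
#' @param ... overrides passed to both designs.
#' @return As [simulate_protocol_pair()].
#' @export
mesc_pair <- function(n_genes = 12000, n_cells = 200, seed = 1L, ...) {
  design_fl <- mesc_design("full_length", n_genes = n_genes,
                           n_cells = n_cells, seed = seed, ...)
  design_umi <- mesc_design("umi", n_genes = n_genes, n_cells = n_cells,
                            seed = .derived_seed(seed, 7), ...)
  truth <- draw_gene_truth(design_fl)
  simulate_protocol_pair(truth, design_fl, design_umi)
}
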