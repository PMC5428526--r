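#!/usr/bin/env Rscript
# Stage 4: combine the protocols on commonly detected genes and compare
# what each protocol detects.
#
# The combined matrix is restricted to genes detected (nonzero in >= 10% of
# cells) in every dataset so that the larger dataset does not dominate gene
# selection; PCA of the log-CPM matrix shows where the cells fall. The
# detection overlap contrasts the two protocols' detected sets, and the
# rank-sum test asks whether the genes detected by only one protocol differ
# in length.
#
#   Rscript analysis/04_combine_overlap.R

suppressPackageStartupMessages(library(sclenbias))

out <- "results/analysis"
fl <- read_count_matrix(file.path(out, "qc", "full_length"), "mtx_triplet")
umi <- read_count_matrix(file.path(out, "qc", "umi"), "mtx_triplet")
fl$cells$dataset_id <- "full_length"
umi$cells$dataset_id <- "umi"
dir.create(file.path(out, "overlap"), showWarnings = FALSE)

shared <- common_genes(list(fl, umi))
combined <- combine_datasets(list(fl, umi), shared)
message(sprintf("%d genes commonly detected across both datasets, %d cells",
                length(shared), ncol(combined$counts)))

emb <- pca_embedding(t(log_cpm(combined$counts)), 3)
coords <- data.frame(cell_id = combined$cells$cell_id,
                     dataset_id = combined$cells$dataset_id,
                     protocol = combined$cells$protocol,
                     emb$coordinates)
utils::write.table(coords, file.path(out, "overlap", "pca_coordinates.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
pc1_gap <- abs(mean(emb$coordinates[combined$cells$protocol == "umi", 1]) -
               mean(emb$coordinates[combined$cells$protocol == "full_length", 1]))
message(sprintf("PC1 separates the protocols by %.1f units (%.0f%% of variance on PC1)",
                pc1_gap, 100 * emb$variance[1] / sum(emb$variance)))

ov <- detection_overlap(list(umi), list(fl))
lengths <- setNames(fl$genes$length_bp, fl$genes$gene_id)
lengths[umi$genes$gene_id] <- umi$genes$length_bp
regions <- rbind(
  data.frame(gene_id = ov$genes_in_both, region = "in_both"),
  data.frame(gene_id = ov$genes_only_a, region = "umi_only"),
  data.frame(gene_id = ov$genes_only_b, region = "full_length_only"))
regions$length_bp <- lengths[regions$gene_id]
utils::write.table(regions, file.path(out, "overlap", "regions.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

wt <- wilcoxon_rank_sum(lengths[ov$genes_only_a], lengths[ov$genes_only_b])
res <- list(universe_size = ov$universe_size, in_both = ov$in_both,
            umi_only = ov$only_a, full_length_only = ov$only_b,
            umi_only_median_length = median(lengths[ov$genes_only_a]),
            full_length_only_median_length = median(lengths[ov$genes_only_b]),
            length_wilcoxon_p = wt$p_value)
jsonlite::write_json(res, file.path(out, "overlap", "overlap.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf(
  "detected in both: %d; UMI-only: %d (median %d bp); full-length-only: %d (median %d bp)",
  ov$in_both, ov$only_a, round(res$umi_only_median_length),
  ov$only_b, round(res$full_length_only_median_length)))
message(sprintf("rank-sum test on lengths of uniquely detected genes: p = %.3g",
                wt$p_value))
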