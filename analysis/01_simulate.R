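#!/usr/bin/env Rscript
# Stage 1: generate the matched full-length / UMI study pair.
#
# Two datasets share one gene-level truth (lengths, baseline expressions,
# condition fold changes): a deep full-length dataset whose expected read
# counts scale with gene length, and a shallow UMI dataset whose molecule
# counts do not. Everything downstream (QC, bias trends, detection overlap,
# DE) runs off these files, so the whole analysis is reproducible from a
# single seed.
#
#   Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(sclenbias))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pair <- mesc_pair(n_genes = 5000, n_cells = 200, seed = seed)

write_dataset(pair$full_length, file.path(out, "simulate", "full_length"))
write_dataset(pair$umi, file.path(out, "simulate", "umi"))
utils::write.table(pair$truth$genes,
                   file.path(out, "simulate", "truth_genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("full-length: %d genes x %d cells, median library %s reads",
                nrow(pair$full_length$counts), ncol(pair$full_length$counts),
                format(median(colSums(pair$full_length$counts)), big.mark = ",")))
message(sprintf("umi:         %d genes x %d cells, median library %s molecules",
                nrow(pair$umi$counts), ncol(pair$umi$counts),
                format(median(colSums(pair$umi$counts)), big.mark = ",")))
message(sprintf("%d of %d ordinary genes carry a condition effect",
                sum(pair$truth$genes$log2_fc != 0),
                sum(pair$truth$genes$gene_class == "ordinary")))
message("wrote ", file.path(out, "simulate"))
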