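#!/usr/bin/env Rscript
# Stage 2: cell and gene quality control.
#
# Cells are kept when their dropout fraction, library size and spike-in
# fraction are acceptable; genes are kept when they have at most 90% zeroes
# across the retained cells, are neither mitochondrial nor ribosomal, carry
# a curated identifier and a known length. Spike-ins leave the analysis
# matrix here (their totals stay on the cell table).
#
#   Rscript analysis/02_qc.R

suppressPackageStartupMessages(library(sclenbias))

out <- "results/analysis"
for (name in c("full_length", "umi")) {
  raw <- read_count_matrix(file.path(out, "simulate", name), "mtx_triplet")
  filtered <- filter_genes(filter_cells(raw, qc_thresholds()),
                           gene_filter_policy())
  write_dataset(filtered, file.path(out, "qc", name))
  rep <- qc_report(raw, filtered)
  write_qc_report(rep, file.path(out, "qc", paste0(name, "_report")))
  message(sprintf("%s: %d cells and %d genes for further analysis (%d genes removed)",
                  name, ncol(filtered$counts), nrow(filtered$counts),
                  nrow(raw$counts) - nrow(filtered$counts)))
}
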