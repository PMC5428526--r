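#!/usr/bin/env Rscript
# Stage 6: are the uniquely detected genes biologically active?
#
# Two-group differential expression between the culture conditions within
# each protocol (median-ratio normalization, rank-sum test, BH FDR), with a
# log2-fold-change cut-off of 1 for the deep full-length dataset and 0.5
# for the shallow UMI dataset, then the fraction of each uniquely detected
# region that is significantly differentially expressed.
#
#   Rscript analysis/06_differential_expression.R

suppressPackageStartupMessages(library(sclenbias))

out <- "results/analysis"
regions <- utils::read.delim(file.path(out, "overlap", "regions.tsv"))
dir.create(file.path(out, "de"), showWarnings = FALSE)

cutoffs <- c(full_length = 1, umi = 0.5)
unique_region <- c(full_length = "full_length_only", umi = "umi_only")
for (name in c("full_length", "umi")) {
  ds <- read_count_matrix(file.path(out, "qc", name), "mtx_triplet")
  de <- suppressWarnings(de_two_group(ds, lfc_cutoff = cutoffs[[name]]))
  utils::write.table(de, file.path(out, "de", paste0(name, "_de.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d of %d genes DE at FDR 0.05 with |lfc| >= %.1f (%.0f%%)",
                  name, sum(de$significant), nrow(de), cutoffs[[name]],
                  100 * mean(de$significant)))
  set <- intersect(regions$gene_id[regions$region == unique_region[[name]]],
                   de$gene_id)
  if (length(set) > 0) {
    fr <- de_fraction_in_set(de, set)
    message(sprintf(
      "  uniquely detected genes DE: %d/%d (%.0f%%) vs %d/%d (%.0f%%) overall",
      fr$n_set_significant, fr$n_set, 100 * fr$set_fraction,
      fr$n_significant, fr$n_tested, 100 * fr$overall_fraction))
  }
}
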