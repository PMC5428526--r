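# sclenbias

Gene length and detection bias in single-cell RNA-seq protocols.

Full-length scRNA-seq library preparations fragment cDNA, so a long
transcript yields more reads — and is easier to detect — than a short one
at the same molecular abundance. UMI-based protocols count molecules and
carry no such length dependence, but dividing UMI counts by gene length
(RPKM) artificially inflates short genes. `sclenbias` is for analysts
comparing or combining datasets across the two protocol families: it
quantifies the length bias, compares which genes each protocol detects,
and ships a mechanistic simulator so every claim is testable against a
known truth.

## What it computes

For a filtered count matrix, per gene *g*: the mean over cells of
log2(CPM + 1), the dropout rate (fraction of cells with a zero count) and
the mean log2(RPKM + 1), where RPKM<sub>gc</sub> = CPM<sub>gc</sub> /
(L<sub>g</sub>/1000) with L<sub>g</sub> the union-exon length. Genes are
split into 10 equal-occupancy length bins (per-bin quartiles reproduce the
classic three-panel boxplot view) and each trend is summarized as a
Spearman rank correlation with gene length: `rho_count`, `rho_dropout`,
`rho_rpkm`.

Detection comparisons call a gene detected when it is nonzero in at least
⌈0.10·cells⌉ cells, intersect detected sets within protocol groups, and
compare the uniquely detected regions by a Wilcoxon rank-sum test on gene
lengths, hypergeometric (upper-tail) enrichment against GMT gene-set
categories with Benjamini–Hochberg FDR, and a variance-ratio F-test on the
spread of per-category median lengths. A two-group differential-expression
stage (median-of-ratios size factors, rank-sum test, BH FDR, post-hoc
log-fold-change cutoff) measures how many uniquely detected genes are
condition-responsive.

The simulator draws gene lengths and expressions from log-normals, NB
molecule counts per cell, and Poisson reads with expected value
`molecules × depth × (length/L0)^alpha` — `alpha = 1` is fragmentation
(full-length), `alpha = 0` is molecule counting (UMI). See the methods
vignette (`vignettes/length-bias-methods.Rmd`) for the model, parameter
defaults and their rationale.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
protocol pair (5000 genes, 200 cells per protocol, seed 1):

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_qc.R
Rscript analysis/03_length_bias.R
Rscript analysis/04_combine_overlap.R
Rscript analysis/05_detection_stats.R
Rscript analysis/06_differential_expression.R
```

Stage 3 prints the trend statistics:

```
full_length: rho(length, log counts) = +0.58; rho(length, dropout) = -0.35; rho(length, log RPKM) = +0.07
  bin 1 median dropout 0.65 vs bin 10 median dropout 0.27
umi: rho(length, log counts) = +0.02; rho(length, dropout) = -0.03; rho(length, log RPKM) = -0.44
  bin 1 median dropout 0.61 vs bin 10 median dropout 0.60
```

Read: under fragmentation (full-length) short genes have lower counts and
drop out far more often (dropout falls from 0.65 to 0.27 across the length
bins), and dividing by length (RPKM) flattens the trend. Under molecule
counting (UMI) counts and dropout are length-flat — and it is the RPKM
division itself that manufactures a strong negative trend (−0.44), which
is why UMI data should be reported as normalized counts, not RPKM.

Stage 4 compares what the two protocols detect:

```
detected in both: 3889; UMI-only: 24 (median 200 bp); full-length-only: 610 (median 4159 bp)
rank-sum test on lengths of uniquely detected genes: p = 1.26e-16
```

The shallow UMI dataset still detects two dozen genes the deep full-length
dataset misses, and they are the shortest genes in the transcriptome; the
full-length-only genes are long. Stage 5 shows the UMI-only set enriching
in short-gene categories, and stage 6 reports the fraction of each
uniquely detected region that is differentially expressed between the two
culture conditions.

Equivalent one-shot runs go through a YAML config and `run_pipeline()`;
QC presets for the eight published dataset profiles are available via
`qc_preset()` (e.g. `"kolodziejczyk"`: dropout ≤ 0.80 and ≥ 5×10⁵ reads).

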