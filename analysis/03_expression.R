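#!/usr/bin/env Rscript
# Differential expression of expressed lncRNAs between SOL and EDL.

source("analysis/00_common.R")
out <- results_dir()
study <- conjoint_study()

sm <- study$counts$samples
ids <- study$counts$truth$transcript_id
input_cols <- sm$library_id[sm$assay == "Input"]
de <- differential_expression(
  study$counts$counts_input[ids, input_cols],
  groups = factor(sm$tissue[sm$assay == "Input"], levels = study$spec$tissues))
write_table_tsv(de, file.path(out, "03_de_table.tsv"))

cat("tested lncRNAs:", nrow(de), "\n")
cat("differentially expressed (padj < 0.05, |log2FC| >= 1):",
    sum(de$de_flag != "ns"), "( up:", sum(de$de_flag == "up"),
    "/ down:", sum(de$de_flag == "down"), ")\n")
planted <- study$counts$truth$transcript_id[study$counts$truth$quadrant != "none"]
cat("planted DE recovered:", sum(de$de_flag[match(planted, de$transcript_id)] != "ns"),
    "of", length(planted), "\n")
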