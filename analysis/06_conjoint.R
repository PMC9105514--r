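#!/usr/bin/env Rscript
# Conjoint MeRIP/RNA analysis: differential methylation and the
# four-quadrant classification of dme-lncRNAs.

source("analysis/00_common.R")
out <- results_dir()
study <- conjoint_study()

sm <- study$counts$samples
ids <- study$counts$truth$transcript_id
tis <- study$spec$tissues
input_cols <- sm$library_id[sm$assay == "Input"]
de <- differential_expression(
  study$counts$counts_input[ids, input_cols],
  groups = factor(sm$tissue[sm$assay == "Input"], levels = tis))
pool <- function(mat, assay, tissue) {
  rowSums(mat[ids, sm$library_id[sm$assay == assay & sm$tissue == tissue]])
}
dm <- differential_methylation(
  ip_a = pool(study$counts$counts_ip, "IP", tis[1]),
  input_a = pool(study$counts$counts_input, "Input", tis[1]),
  ip_b = pool(study$counts$counts_ip, "IP", tis[2]),
  input_b = pool(study$counts$counts_input, "Input", tis[2]),
  transcript_id = ids)
write_table_tsv(dm, file.path(out, "06_dm_table.tsv"))

fq <- four_quadrant(de, dm)
write_table_tsv(fq$records, file.path(out, "06_dme_table.tsv"))
write_table_tsv(tibble::enframe(fq$counts, "quadrant", "n"),
                file.path(out, "06_quadrant_counts.tsv"))

cat("differentially methylated lncRNAs (padj < 0.05):",
    sum(dm$dm_flag != "ns", na.rm = TRUE), "\n")
cat("dme-lncRNAs:", length(fq$dme_ids), "of", sum(de$de_flag != "ns"),
    "DE lncRNAs\n")
cat("quadrants:", paste(names(fq$counts), fq$counts, sep = "=", collapse = ", "), "\n")
planted <- table(study$counts$truth$quadrant)
cat("planted:  ", paste(names(planted), planted, sep = "=", collapse = ", "), "\n")
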