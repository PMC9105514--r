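#!/usr/bin/env Rscript
# Novel-lncRNA discovery: the five-stage filter cascade, positional
# classification, and the combined expressed catalog.

source("analysis/00_common.R")
out <- results_dir()
study <- conjoint_study()

fpkm <- study$counts$fpkm_input
cand_fpkm <- fpkm[intersect(rownames(fpkm),
                            study$annotation$assembled$transcripts$transcript_id), ,
                  drop = FALSE]
disc <- filter_cascade(study$annotation$assembled,
                       study$context$coding_potential, cand_fpkm)
write_table_tsv(disc$report, file.path(out, "02_cascade_report.tsv"))
cat("cascade attrition:\n")
print(as.data.frame(disc$report), row.names = FALSE)

coding <- subset_transcripts(
  study$annotation$reference,
  study$annotation$reference$transcripts$transcript_id[
    study$annotation$reference$transcripts$biotype == "coding"])
annotated <- subset_transcripts(
  study$annotation$reference,
  study$annotation$reference$transcripts$transcript_id[
    study$annotation$reference$transcripts$biotype == "annotated_lncRNA"])
classes <- classify_lncrna(disc$novel, coding)
catalog <- summarize_catalog(disc$novel, annotated, classes)
write_table_tsv(catalog$class_table, file.path(out, "02_position_classes.tsv"))
write_gtf(disc$novel, file.path(out, "02_novel_lncrna.gtf"))

cat("\nnovel lncRNAs:", catalog$n_novel, "| annotated:", catalog$n_annotated,
    "| expressed universe:", catalog$n_expressed, "\n")
cat("positional classes (%):\n")
print(as.data.frame(catalog$class_table), row.names = FALSE)
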