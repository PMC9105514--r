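#!/usr/bin/env Rscript
# Generate the two synthetic studies and export their primary artifacts
# (annotation GTFs, count/FPKM tables, QTL BED, PPI edges, truth tables).

source("analysis/00_common.R")
out <- results_dir("sim")

study <- conjoint_study()
write_gtf(study$annotation$reference, file.path(out, "reference.gtf"))
write_gtf(study$annotation$assembled, file.path(out, "assembled.gtf"))
write_table_tsv(tibble::as_tibble(study$counts$counts_input, rownames = "transcript_id"),
                file.path(out, "counts_input.tsv"))
write_table_tsv(tibble::as_tibble(study$counts$counts_ip, rownames = "transcript_id"),
                file.path(out, "counts_ip.tsv"))
write_table_tsv(study$context$coding_potential, file.path(out, "coding_potential.tsv"))
write_bed(dplyr::rename(study$context$qtl, name = qtl_id), file.path(out, "qtl.bed"))
write_table_tsv(study$context$ppi_edges, file.path(out, "ppi_edges.tsv"))
write_table_tsv(study$context$known_sites, file.path(out, "known_sites_synthetic.tsv"))
write_table_tsv(study$counts$truth, file.path(out, "truth_conjoint.tsv"))

cat("conjoint scenario:",
    nrow(study$annotation$assembled$transcripts), "candidate transcripts;",
    sum(study$counts$truth$quadrant != "none"), "planted DE lncRNAs (",
    sum(study$counts$truth$quadrant %in%
          c("Hyper-Up", "Hypo-Up", "Hyper-Down", "Hypo-Down")), "dme )\n")

assoc <- association_study()
write_table_tsv(assoc$counts$truth, file.path(out, "truth_association.tsv"))
cat("association scenario:", nrow(assoc$counts$truth), "lncRNAs; planted",
    "m6A-expression coupling", assoc$spec$true_m6a_expression_correlation, "\n")
cat("artifacts in", out, "\n")
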