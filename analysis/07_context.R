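#!/usr/bin/env Rscript
# Genomic context of dme-lncRNAs: QTL interval intersection with trait
# categories, and cis potential target genes within 100 kb.

source("analysis/00_common.R")
out <- results_dir()
study <- conjoint_study()
cfg <- run_config()

dme_ids <- study$counts$truth$transcript_id[
  study$counts$truth$quadrant %in% c("Hyper-Up", "Hypo-Up", "Hyper-Down", "Hypo-Down")]
lnc_all <- transcript_set(
  dplyr::bind_rows(study$annotation$assembled$transcripts,
                   study$annotation$reference$transcripts),
  dplyr::bind_rows(study$annotation$assembled$exons,
                   study$annotation$reference$exons))
dme_loci <- locus_spans(subset_transcripts(lnc_all, dme_ids))

qtl_res <- intersect_qtl(dme_loci, study$context$qtl)
write_table_tsv(qtl_res$pairs, file.path(out, "07_qtl_pairs.tsv"))
write_table_tsv(qtl_res$proportions, file.path(out, "07_qtl_proportions.tsv"))
cat(qtl_res$n_lncrna_hit, "of", length(dme_ids),
    "dme-lncRNAs overlap", length(unique(qtl_res$pairs$qtl_id)), "QTLs\n")
cat("QTL category shares:\n")
print(as.data.frame(qtl_res$proportions), row.names = FALSE)

coding <- subset_transcripts(
  study$annotation$reference,
  study$annotation$reference$transcripts$transcript_id[
    study$annotation$reference$transcripts$biotype == "coding"])
gene_loci <- locus_spans(coding, by = "gene_id")
sm <- study$counts$samples
input_cols <- sm$library_id[sm$assay == "Input"]
cg_fpkm <- study$counts$fpkm_input[coding$transcripts$transcript_id, input_cols]
expressed_genes <- coding$transcripts$gene_id[apply(cg_fpkm, 1, max) >= cfg$fpkm_min]

meat_ids <- unique(qtl_res$pairs$transcript_id[
  qtl_res$pairs$category == "meat_and_carcass"])
cis <- find_cis_ptg(dme_loci[dme_loci$transcript_id %in% meat_ids, ],
                    gene_loci, expressed_genes, window = cfg$cis_window_bp)
write_table_tsv(cis, file.path(out, "07_cis_pairs.tsv"))
cat(length(unique(cis$gene_id)), "cis potential target genes for",
    length(unique(cis$lncrna_id)), "meat/carcass-QTL dme-lncRNAs\n")
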