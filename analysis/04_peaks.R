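#!/usr/bin/env Rscript
# m6A peak calling from IP/Input window tracks, MFPKM enrichment, metagene
# and last-exon profiles, and RRACH consensus-motif enrichment.

source("analysis/00_common.R")
out <- results_dir()
study <- conjoint_study()
cfg <- run_config()

expressed <- study$counts$truth$transcript_id
win <- study$counts$windows[study$counts$windows$transcript_id %in% expressed, ]
peaks <- call_peaks(win, cfg)
cat("called", nrow(peaks), "peaks over",
    length(unique(peaks$transcript_id)), "lncRNAs\n")
for (tt in study$spec$tissues) {
  cat("  ", tt, ":", sum(peaks$tissue == tt), "peaks on",
      length(unique(peaks$transcript_id[peaks$tissue == tt])), "lncRNAs\n")
}

lnc_all <- transcript_set(
  dplyr::bind_rows(study$annotation$assembled$transcripts,
                   study$annotation$reference$transcripts),
  dplyr::bind_rows(study$annotation$assembled$exons,
                   study$annotation$reference$exons))
lnc_all <- subset_transcripts(lnc_all, expressed)

# novelty labeling against the synthetic known-site table
gen <- transcript_coords_to_genome(peaks$transcript_id, peaks$summit, lnc_all)
half <- (peaks$end - peaks$start) / 2
genomic <- tibble::tibble(chrom = gen$chrom,
                          start = pmax(0, gen$pos - half),
                          end = gen$pos + half, summit = gen$pos,
                          tissue = peaks$tissue, summit_tx = peaks$summit,
                          source_id = peaks$transcript_id)
labeled <- suppressWarnings(assign_and_label(genomic, lnc_all,
                                             study$context$known_sites))
labeled <- labeled[labeled$transcript_id == labeled$source_id, ]
write_table_tsv(labeled, file.path(out, "04_peaks.tsv"))
cat("novelty:", sum(labeled$novelty == "known"), "known /",
    sum(labeled$novelty == "unknown"), "unknown peaks\n")

# peaks-per-lncRNA histogram
per <- dplyr::count(labeled, tissue, transcript_id)
hist_tbl <- dplyr::count(per, tissue, n, name = "lncRNAs")
write_table_tsv(hist_tbl, file.path(out, "04_peaks_per_lncrna.tsv"))

# metagene + exon-position profile (per summit, transcript coordinates)
prof <- metagene_profile(
  tibble::tibble(transcript_id = labeled$transcript_id,
                 summit = labeled$summit_tx), lnc_all)
write_table_tsv(prof$profile, file.path(out, "04_metagene.tsv"))
cat("summit exon fractions (multi-exon lncRNAs): first",
    round(prof$exon_fractions[["first"]], 3), "/ internal",
    round(prof$exon_fractions[["internal"]], 3), "/ last",
    round(prof$exon_fractions[["last"]], 3), "\n")

# MFPKM enrichment per tissue
sm <- study$counts$samples
for (tt in study$spec$tissues) {
  mf <- mfpkm(
    study$counts$fpkm_ip[expressed, sm$library_id[sm$assay == "IP" & sm$tissue == tt]],
    study$counts$fpkm_input[expressed, sm$library_id[sm$assay == "Input" & sm$tissue == tt]],
    input_floor = cfg$input_fpkm_floor)
  write_table_tsv(mf, file.path(out, paste0("04_mfpkm_", tt, ".tsv")))
}

# RRACH motif enrichment on a sequence-bearing simulation (smaller genome)
seq_spec <- simulation_spec(n_coding_genes = 40, n_lncrna = 300, n_qtl = 20,
                            quadrant_counts = c(0, 0, 0, 0), n_de_only = 0,
                            seed = 11)
seq_ann <- generate_annotation(seq_spec, emit_sequence = TRUE)
pk <- seq_ann$truth$peaks
pk <- pk[pk$transcript_id %in% seq_ann$assembled$transcripts$transcript_id, ]
seqs <- peak_sequences(
  tibble::tibble(transcript_id = pk$transcript_id, summit = pk$summit_tx),
  seq_ann$assembled, seq_ann$genome, half_width = 50)
set.seed(11)
mot <- motif_enrichment(seqs, "RRACH")
cat(sprintf("RRACH enrichment: %d/%d peak sequences vs %d/%d shuffled (OR %.1f, p = %.3g)\n",
            mot$target_hits, mot$n_target, mot$background_hits,
            mot$n_background, mot$odds_ratio, mot$pvalue))
write_table_tsv(tibble::tibble(consensus = "RRACH",
                               odds_ratio = mot$odds_ratio, pvalue = mot$pvalue,
                               target_hits = mot$target_hits,
                               n_target = mot$n_target,
                               background_hits = mot$background_hits,
                               n_background = mot$n_background),
                file.path(out, "04_motif_enrichment.tsv"))
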