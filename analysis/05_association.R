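#!/usr/bin/env Rscript
# m6A-expression association: L/M/H sets, expression-divergence quantile
# groups, Mann-Kendall trends, and the fold-change correlation.

source("analysis/00_common.R")
out <- results_dir()
assoc <- association_study()

cts <- assoc$counts
sm <- cts$samples
ids <- cts$truth$transcript_id
mf <- lapply(assoc$spec$tissues, function(tt) {
  mfpkm(cts$fpkm_ip[ids, sm$library_id[sm$assay == "IP" & sm$tissue == tt]],
        cts$fpkm_input[ids, sm$library_id[sm$assay == "Input" & sm$tissue == tt]])
})
m6a_fc <- stats::setNames(log2(mf[[1]]$mfpkm / mf[[2]]$mfpkm), ids)
inc <- sm$library_id[sm$assay == "Input" & sm$tissue == assoc$spec$tissues[1]]
ine <- sm$library_id[sm$assay == "Input" & sm$tissue == assoc$spec$tissues[2]]

res <- associate_m6a_expression(
  ids,
  modified_in_a = ids[cts$truth$modified_sol],
  modified_in_b = ids[cts$truth$modified_edl],
  mean_fpkm_a = rowMeans(cts$fpkm_input[ids, inc]),
  mean_fpkm_b = rowMeans(cts$fpkm_input[ids, ine]),
  m6a_log2fc = m6a_fc)

write_table_tsv(res$homeostasis, file.path(out, "05_homeostasis.tsv"))
cat("L/M/H set sizes:", paste(names(res$lmh_sizes), res$lmh_sizes,
                              sep = "=", collapse = ", "), "\n")
cat("divergence groups:", paste(names(res$group_sizes), res$group_sizes,
                                sep = "=", collapse = ", "), "\n")
cat(sprintf("divergence trend over L<M<H: S = %d, p = %.3g\n",
            res$trend_divergence$S, res$trend_divergence$pvalue))
cat(sprintf("both-tissue modification rate over Low<Median<High: S = %d, p = %.3g\n",
            res$trend_modification$S, res$trend_modification$pvalue))
cat(sprintf("m6A-expression fold-change correlation (H set): r = %.3f, p = %.3g, n = %d\n",
            res$correlation$r, res$correlation$pvalue, res$correlation$n))
med <- tapply(res$homeostasis$mean_expression, res$homeostasis$set_label, median)
cat("median expression by set: ",
    paste(names(med), round(med, 1), sep = "=", collapse = ", "), "\n")
write_table_tsv(
  tibble::tibble(statistic = c("r", "pvalue", "n"),
                 value = c(res$correlation$r, res$correlation$pvalue,
                           res$correlation$n)),
  file.path(out, "05_correlation.tsv"))
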