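#' Differential methylation between tissues
#'
#' Per-lncRNA comparison of pooled IP/Input counts between tissues:
#' `meth_log2fc = log2((ip_a/input_a) / (ip_b/input_b))` with zero counts
#' floored at 0.5, and a two-sided Fisher exact test on the 2x2 table
#' `(ip_a, input_a; ip_b, input_b)`, BH-adjusted across lncRNAs. Rows with
#' all-zero counts yield `NA` records.
#'
#' @param ip_a,input_a,ip_b,input_b Pooled (replicate-summed) counts per
#'   lncRNA for tissues A and B.
#' @param transcript_id Ids aligned with the count vectors.
#' @param config A [run_config]; `dm_padj` sets the significance threshold.
#' @return Tibble with `transcript_id`, `meth_log2fc`, `pvalue`, `padj`,
#'   `dm_flag` (`hyper`, `hypo`, `ns`).
#' @export
differential_methylation <- function(ip_a, input_a, ip_b, input_b,
                                     transcript_id = names(ip_a),
                                     config = run_config()) {
  n <- length(ip_a)
  stopifnot(length(input_a) == n, length(ip_b) == n, length(input_b) == n)
  all_zero <- (ip_a + input_a + ip_b + input_b) == 0
  fa <- pmax(ip_a, 0.5) / pmax(input_a, 0.5)
  fb <- pmax(ip_b, 0.5) / pmax(input_b, 0.5)
  lfc <- log2(fa / fb)
  pvalue <- vapply(seq_len(n), function(i) {
    if (all_zero[i]) return(NA_real_)
    stats::fisher.test(matrix(c(ip_a[i], input_a[i], ip_b[i], input_b[i]),
                              nrow = 2))$p.value
  }, 0)
  padj <- benjamini_hochberg(pvalue)
  lfc[all_zero] <- NA_real_
  flag <- rep("ns", n)
  sig <- !is.na(padj) & padj < config$dm_padj
  flag[sig & lfc > 0] <- "hyper"
  flag[sig & lfc < 0] <- "hypo"
  tibble::tibble(transcript_id = transcript_id, meth_log2fc = lfc,
                 pvalue = pvalue, padj = padj, dm_flag = flag)
}

#' Four-quadrant conjoint classification
#'
#' Intersects the differential expression and differential methylation
#' tables: lncRNAs significant on both axes are dme-lncRNAs, labelled by the
#' sign pair (methylation direction x expression direction) as `Hyper-Up`,
#' `Hypo-Up`, `Hyper-Down` or `Hypo-Down`.
#'
#' @param de Differential expression table from [differential_expression].
#' @param dm Differential methylation table from [differential_methylation].
#' @param config A [run_config].
#' @return A list with `records` (per-lncRNA joint table with `quadrant`),
#'   `dme_ids`, and `counts` (named quadrant counts plus `total`).
#' @export
four_quadrant <- function(de, dm, config = run_config()) {
  joint <- dplyr::inner_join(
    dplyr::select(de, "transcript_id", expr_log2fc = "log2fc",
                  expr_padj = "padj", de_flag = "de_flag"),
    dplyr::select(dm, "transcript_id", "meth_log2fc", meth_padj = "padj"),
    by = "transcript_id"
  )
  expr_sig <- joint$de_flag != "ns"
  meth_sig <- !is.na(joint$meth_padj) & joint$meth_padj < config$dm_padj
  dme <- expr_sig & meth_sig
  stopifnot(!any(dme & joint$meth_log2fc == 0)) # sign must be defined
  quadrant <- rep("none", nrow(joint))
  quadrant[dme & joint$meth_log2fc > 0 & joint$de_flag == "up"] <- "Hyper-Up"
  quadrant[dme & joint$meth_log2fc < 0 & joint$de_flag == "up"] <- "Hypo-Up"
  quadrant[dme & joint$meth_log2fc > 0 & joint$de_flag == "down"] <- "Hyper-Down"
  quadrant[dme & joint$meth_log2fc < 0 & joint$de_flag == "down"] <- "Hypo-Down"
  joint$quadrant <- quadrant
  counts <- c(
    `Hyper-Up` = sum(quadrant == "Hyper-Up"),
    `Hypo-Up` = sum(quadrant == "Hypo-Up"),
    `Hyper-Down` = sum(quadrant == "Hyper-Down"),
    `Hypo-Down` = sum(quadrant == "Hypo-Down")
  )
  list(records = tibble::as_tibble(joint),
       dme_ids = joint$transcript_id[dme],
       counts = c(counts, total = sum(counts)))
}
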