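#' Fragments per kilobase per million (FPKM)
#'
#' `FPKM = counts * 1e9 / (library_size * length_nt)`. Scale-invariant:
#' multiplying counts and library sizes by a common factor leaves FPKM
#' unchanged.
#'
#' @param counts Count matrix, transcripts x samples (rownames = ids).
#' @param lengths Named numeric vector of transcript lengths (nt) > 0.
#' @param library_sizes Optional per-sample library sizes; defaults to the
#'   column sums of `counts`. Must be > 0.
#' @return FPKM matrix with the dimensions of `counts`.
#' @export
compute_fpkm <- function(counts, lengths, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  lens <- if (!is.null(names(lengths))) lengths[rownames(counts)] else lengths
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("transcript lengths must be > 0")
  }
  sweep(counts, 2, library_sizes, "/") * 1e9 / lens
}

#' Median-of-ratios size factors
#'
#' @param counts Count matrix, transcripts x samples.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_geo <- rowMeans(log(counts))
  sf <- apply(counts, 2, function(col) {
    r <- log(col) - log_geo
    exp(stats::median(r[is.finite(r)]))
  })
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment; monotone on the sorted
#' sequence and capped at 1. `NA` values propagate.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise `>=` the input.
#' @export
benjamini_hochberg <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential expression between two tissues
#'
#' A negative-binomial Wald test on median-of-ratios normalized counts with
#' method-of-moments dispersion (floored at 1e-8). The log2 fold change is
#' computed on group means with a pseudo-count of 1 and compares the *first*
#' factor level against the second (positive = up in the first level).
#' Transcripts whose maximum FPKM over samples is below the expression floor
#' are excluded before testing. A precomputed table (id, log2fc, pvalue) may
#' be supplied instead to reproduce an external engine's results.
#'
#' @param counts Count matrix, transcripts x samples.
#' @param groups Factor of length `ncol(counts)` with two levels, each with
#'   at least two replicates.
#' @param config A [run_config].
#' @param fpkm Optional FPKM matrix used for the expression floor.
#' @param precomputed Optional tibble (`transcript_id`, `log2fc`, `pvalue`)
#'   bypassing the internal test; BH adjustment and flags are still applied.
#' @return Tibble with `transcript_id`, `base_mean`, `log2fc`, `pvalue`,
#'   `padj` and `de_flag` (`up`, `down`, `ns`).
#' @export
differential_expression <- function(counts, groups, config = run_config(),
                                    fpkm = NULL, precomputed = NULL) {
  if (!is.null(precomputed)) {
    out <- tibble::as_tibble(precomputed)
    out$padj <- benjamini_hochberg(out$pvalue)
    out$de_flag <- de_flags(out$log2fc, out$padj, config)
    return(out)
  }
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 replicates")
  if (!is.null(fpkm)) {
    keep <- apply(as.matrix(fpkm)[rownames(counts), , drop = FALSE], 1, max) >=
      config$fpkm_min
    counts <- counts[keep, , drop = FALSE]
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  ga <- groups == levels(groups)[1]
  gb <- !ga
  na <- sum(ga)
  nb <- sum(gb)
  ma <- rowMeans(norm[, ga, drop = FALSE])
  mb <- rowMeans(norm[, gb, drop = FALSE])
  va <- rowSums((norm[, ga, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((norm[, gb, drop = FALSE] - mb)^2) / (nb - 1)
  mu <- (na * ma + nb * mb) / (na + nb)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  phi <- pmax((s2 - mu) / mu^2, 1e-8)
  phi[!is.finite(phi)] <- 1e-8
  log2fc <- log2((ma + 1) / (mb + 1))
  var_ma <- (ma + phi * ma^2) / na
  var_mb <- (mb + phi * mb^2) / nb
  se <- sqrt(var_ma / ((ma + 1)^2) + var_mb / ((mb + 1)^2)) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * stats::pnorm(-abs(z))
  padj <- benjamini_hochberg(pvalue)
  out <- tibble::tibble(
    transcript_id = rownames(counts),
    base_mean = unname(mu), log2fc = unname(log2fc),
    pvalue = unname(pvalue), padj = unname(padj),
    de_flag = unname(de_flags(log2fc, padj, config))
  )
  log_stage("differential_expression", nrow(counts),
            sum(out$de_flag != "ns"), config)
  out
}

# Direction flags from adjusted p and fold change per the study thresholds.
de_flags <- function(log2fc, padj, config) {
  flag <- rep("ns", length(log2fc))
  sig <- !is.na(padj) & padj < config$de_padj
  flag[sig & log2fc >= config$de_abs_log2fc] <- "up"
  flag[sig & log2fc <= -config$de_abs_log2fc] <- "down"
  flag
}
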