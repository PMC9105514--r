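#' Classify lncRNAs by m6A modification across tissues (L/M/H sets)
#'
#' `H` = modified in both tissues, `M` = modified in exactly one, `L` =
#' modified in neither; the three sets partition the expressed universe.
#'
#' @param expressed_ids Character vector of expressed lncRNA ids.
#' @param modified_in_a,modified_in_b Ids with m6A peaks in each tissue;
#'   must be subsets of `expressed_ids`.
#' @return A list with `labels` (tibble `transcript_id`, `set_label`) and
#'   `sizes` (named vector `L`, `M`, `H` summing to the universe size).
#' @export
classify_lmh <- function(expressed_ids, modified_in_a, modified_in_b) {
  stray <- setdiff(union(modified_in_a, modified_in_b), expressed_ids)
  if (length(stray) > 0) {
    stop("modified id(s) not in expressed universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  in_a <- expressed_ids %in% modified_in_a
  in_b <- expressed_ids %in% modified_in_b
  label <- ifelse(in_a & in_b, "H", ifelse(in_a | in_b, "M", "L"))
  sizes <- c(L = sum(label == "L"), M = sum(label == "M"), H = sum(label == "H"))
  list(labels = tibble::tibble(transcript_id = expressed_ids, set_label = label),
       sizes = sizes)
}

#' Expression divergence between tissues
#'
#' Absolute log2 difference of tissue-mean FPKM with a pseudo-count of 1:
#' `|log2(a + 1) - log2(b + 1)|`. Symmetric in its arguments and zero for
#' equal means.
#'
#' @param mean_fpkm_a,mean_fpkm_b Non-negative tissue-mean FPKM vectors.
#' @return Non-negative divergence vector.
#' @export
expression_divergence <- function(mean_fpkm_a, mean_fpkm_b) {
  if (any(mean_fpkm_a < 0, na.rm = TRUE) || any(mean_fpkm_b < 0, na.rm = TRUE)) {
    stop("FPKM values must be non-negative")
  }
  abs(log2(mean_fpkm_a + 1) - log2(mean_fpkm_b + 1))
}

#' Quartile grouping into Low / Median / High
#'
#' Values are ranked ascending with ties broken by the stable input order;
#' `Low` takes ranks `<= ceiling(0.25 n)`, `High` takes ranks
#' `> floor(0.75 n)`, `Median` the remainder.
#'
#' @param values Numeric vector, `n >= 4`.
#' @param labels Group labels (low, middle, high).
#' @return A list with `groups` (character vector along `values`) and
#'   `sizes` (named vector in label order).
#' @export
quantile_groups <- function(values, labels = c("Low", "Median", "High")) {
  n <- length(values)
  if (n < 4) stop("need at least 4 values to form quartile groups")
  rank_idx <- order(values, seq_len(n)) # stable tie-break by position
  ranks <- integer(n)
  ranks[rank_idx] <- seq_len(n)
  lo_cut <- ceiling(0.25 * n)
  hi_cut <- floor(0.75 * n)
  groups <- ifelse(ranks <= lo_cut, labels[1],
                   ifelse(ranks > hi_cut, labels[3], labels[2]))
  sizes <- stats::setNames(
    c(sum(groups == labels[1]), sum(groups == labels[2]), sum(groups == labels[3])),
    labels)
  list(groups = groups, sizes = sizes)
}

# Exact null distribution of the Mann-Kendall S for n distinct values:
# S = C(n,2) - 2 * inversions, and the inversion counts of permutations
# follow the Mahonian distribution (convolution of uniform blocks).
mk_exact_pvalue <- function(s_obs, n) {
  counts <- 1
  for (i in 2:n) {
    block <- rep(1, i)
    new <- rep(0, length(counts) + i - 1)
    for (j in seq_len(i)) {
      idx <- seq_along(counts) + j - 1
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  n_pairs <- n * (n - 1) / 2
  s_vals <- n_pairs - 2 * (seq_along(counts) - 1)
  sum(counts[abs(s_vals) >= abs(s_obs)]) / sum(counts)
}

#' Mann-Kendall trend test
#'
#' Two-sided trend test on an ordered sequence: `S` is the sum of signs over
#' all ordered pairs. For small samples (`n <= 10`) without ties the p-value
#' is exact, from the permutation null distribution of `S`; otherwise it uses
#' the normal approximation with tie-corrected variance and continuity
#' correction. An all-tied sequence returns `S = 0`, `p = 1`.
#'
#' @param values Numeric vector ordered by the trend variable (e.g. group
#'   rank); at least 3 observations.
#' @return A list with `S`, `var_s`, `z` and `pvalue`.
#' @export
mann_kendall <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 observations")
  # S = sum over i < j of sgn(x_j - x_i); computed without the n x n outer
  # matrix so the test scales to catalog-sized sequences
  s <- sum(vapply(2:n, function(j) {
    sum(sign(values[j] - values[seq_len(j - 1)]))
  }, 0))
  ties <- table(values)
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_s <= 0) {
    return(list(S = s, var_s = 0, z = 0, pvalue = 1))
  }
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  if (n <= 10 && length(ties) == n) {
    p <- mk_exact_pvalue(s, n)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(S = s, var_s = var_s, z = z, pvalue = min(1, p))
}

#' Correlation of m6A-level and expression fold changes
#'
#' Pearson product-moment correlation between per-lncRNA log2 fold changes
#' of the m6A level (MFPKM) and of expression between the two tissues, with
#' the p-value from the t distribution. `NA` pairs are dropped.
#'
#' @param m6a_log2fc,expression_log2fc Paired numeric vectors.
#' @return A list with `r`, `pvalue` and `n` (pairs used).
#' @export
m6a_expression_correlation <- function(m6a_log2fc, expression_log2fc) {
  ok <- is.finite(m6a_log2fc) & is.finite(expression_log2fc)
  x <- m6a_log2fc[ok]
  y <- expression_log2fc[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the fold-change vectors")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = length(x))
}

#' Full m6A-expression association analysis
#'
#' Bundles the association stage: L/M/H classification, expression
#' divergence and its quartile groups, Mann-Kendall trends of divergence
#' (over L/M/H) and of the both-tissue modification rate (over divergence
#' groups), and the fold-change correlation over lncRNAs with measurable
#' enrichment in both tissues.
#'
#' @param expressed_ids Expressed lncRNA universe.
#' @param modified_in_a,modified_in_b Modified id sets per tissue.
#' @param mean_fpkm_a,mean_fpkm_b Named tissue-mean FPKM vectors over the
#'   universe.
#' @param m6a_log2fc Named vector of log2 MFPKM fold changes (NA where
#'   enrichment is undefined).
#' @return A list with `homeostasis` (per-lncRNA table), `lmh_sizes`,
#'   `group_sizes`, `trend_divergence`, `trend_modification`, `correlation`.
#' @export
associate_m6a_expression <- function(expressed_ids, modified_in_a, modified_in_b,
                                     mean_fpkm_a, mean_fpkm_b, m6a_log2fc) {
  lmh <- classify_lmh(expressed_ids, modified_in_a, modified_in_b)
  div <- expression_divergence(mean_fpkm_a[expressed_ids], mean_fpkm_b[expressed_ids])
  qg <- quantile_groups(div)
  homeostasis <- tibble::tibble(
    transcript_id = expressed_ids,
    set_label = lmh$labels$set_label,
    divergence = as.numeric(div),
    divergence_group = qg$groups,
    mean_expression = as.numeric((mean_fpkm_a[expressed_ids] +
                                    mean_fpkm_b[expressed_ids]) / 2)
  )
  # divergence ordered by L < M < H set rank
  set_rank <- c(L = 1, M = 2, H = 3)[homeostasis$set_label]
  trend_div <- mann_kendall(homeostasis$divergence[order(set_rank,
                                                         seq_along(set_rank))])
  # both-tissue modification indicator ordered by increasing divergence;
  # the trend test then asks whether modification falls off with divergence
  h_ind <- as.numeric(homeostasis$set_label == "H")
  trend_mod <- mann_kendall(h_ind[order(homeostasis$divergence,
                                        seq_along(h_ind))])
  expr_fc <- log2((mean_fpkm_a[expressed_ids] + 1) /
                    (mean_fpkm_b[expressed_ids] + 1))
  # the m6A-level fold change is only meaningful for lncRNAs methylated in
  # both tissues (the H set); others contribute no pair
  m6a_fc <- m6a_log2fc[expressed_ids]
  m6a_fc[lmh$labels$set_label != "H"] <- NA
  correlation <- m6a_expression_correlation(m6a_fc, expr_fc)
  list(homeostasis = homeostasis, lmh_sizes = lmh$sizes,
       group_sizes = qg$sizes, trend_divergence = trend_div,
       trend_modification = trend_mod, correlation = correlation)
}
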