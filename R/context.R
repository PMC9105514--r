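#' Intersect lncRNA loci with QTL intervals
#'
#' Reports a pair for every lncRNA locus overlapping a QTL interval by at
#' least 1 bp (strand ignored; QTL records are unstranded), plus the trait-
#' category proportions over all pairs.
#'
#' @param lncrna_loci Interval table with a `transcript_id` column.
#' @param qtl Interval table with `qtl_id` and `category` columns.
#' @return A list with `pairs` (tibble `transcript_id`, `qtl_id`,
#'   `category`), `proportions` (per-category share of pairs, summing to 1),
#'   and `n_lncrna_hit`.
#' @export
intersect_qtl <- function(lncrna_loci, qtl) {
  shared <- intersect(unique(lncrna_loci$chrom), unique(qtl$chrom))
  if (length(shared) == 0 && nrow(lncrna_loci) > 0 && nrow(qtl) > 0) {
    warning("no shared chromosome names; lncRNA: ",
            paste(utils::head(unique(lncrna_loci$chrom), 3), collapse = ","),
            " vs QTL: ", paste(utils::head(unique(qtl$chrom), 3), collapse = ","))
  }
  lg <- intervals_to_granges(lncrna_loci)
  qg <- intervals_to_granges(qtl)
  # seqlevel mismatches are already reported above in domain terms
  hits <- suppressWarnings(GenomicRanges::findOverlaps(lg, qg, ignore.strand = TRUE))
  pairs <- tibble::tibble(
    transcript_id = lncrna_loci$transcript_id[S4Vectors::queryHits(hits)],
    qtl_id = qtl$qtl_id[S4Vectors::subjectHits(hits)],
    category = qtl$category[S4Vectors::subjectHits(hits)]
  )
  proportions <- tibble::tibble(category = character(), n = integer(),
                                proportion = numeric())
  if (nrow(pairs) > 0) {
    proportions <- dplyr::count(pairs, .data$category, name = "n")
    proportions$proportion <- proportions$n / sum(proportions$n)
    proportions <- dplyr::arrange(proportions, dplyr::desc(.data$proportion))
  }
  list(pairs = pairs, proportions = proportions,
       n_lncrna_hit = length(unique(pairs$transcript_id)))
}

#' Find cis potential target genes within a window
#'
#' An expressed protein-coding gene is a cis potential target gene (PTG) of
#' a lncRNA when the gap between the two loci is at most `window` bp
#' (inclusive at exactly the window; 0 for overlapping loci). Distances are
#' measured between locus boundaries, matching interval-tool semantics.
#'
#' @param lncrna_loci Interval table with `transcript_id`.
#' @param gene_loci Interval table of protein-coding gene spans with
#'   `gene_id`.
#' @param expressed_gene_ids Gene ids passing the expression filter.
#' @param window Maximum boundary gap in bp.
#' @return Tibble of `CisPair`s: `lncrna_id`, `gene_id`, `distance_bp`.
#' @export
find_cis_ptg <- function(lncrna_loci, gene_loci, expressed_gene_ids,
                         window = 100000) {
  genes <- gene_loci[gene_loci$gene_id %in% expressed_gene_ids, , drop = FALSE]
  lg <- intervals_to_granges(lncrna_loci)
  gg <- intervals_to_granges(genes)
  hits <- GenomicRanges::findOverlaps(lg, gg, maxgap = window,
                                      ignore.strand = TRUE)
  d <- GenomicRanges::distance(lg[S4Vectors::queryHits(hits)],
                               gg[S4Vectors::subjectHits(hits)],
                               ignore.strand = TRUE)
  keep <- !is.na(d) & d <= window
  tibble::tibble(
    lncrna_id = lncrna_loci$transcript_id[S4Vectors::queryHits(hits)][keep],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)][keep],
    distance_bp = as.numeric(d[keep])
  )
}

#' Expression-direction concordance of cis pairs
#'
#' Cross-tabulates the differential-expression directions of lncRNAs and
#' their cis target genes; concordant = both up or both down.
#'
#' @param cis_pairs Tibble from [find_cis_ptg].
#' @param lncrna_de DE table for lncRNAs (ids + `de_flag`).
#' @param gene_de DE table for genes (`transcript_id` or `gene_id` + `de_flag`).
#' @return Tibble of direction pairs with counts and a `concordant` flag.
#' @export
cis_direction_table <- function(cis_pairs, lncrna_de, gene_de) {
  gid_col <- if ("gene_id" %in% names(gene_de)) "gene_id" else "transcript_id"
  tab <- dplyr::inner_join(
    cis_pairs,
    dplyr::select(lncrna_de, lncrna_id = "transcript_id", lnc_flag = "de_flag"),
    by = "lncrna_id")
  tab <- dplyr::inner_join(
    tab,
    dplyr::select(gene_de, gene_id = dplyr::all_of(gid_col), gene_flag = "de_flag"),
    by = "gene_id")
  out <- dplyr::count(tab, .data$lnc_flag, .data$gene_flag, name = "n")
  out$concordant <- out$lnc_flag == out$gene_flag & out$lnc_flag != "ns"
  out
}

#' Locus spans of a transcript set
#'
#' @param tset A [transcript_set].
#' @param by Group by `"transcript_id"` or `"gene_id"`.
#' @return Interval table with one span per transcript or gene.
#' @export
locus_spans <- function(tset, by = c("transcript_id", "gene_id")) {
  by <- match.arg(by)
  src <- dplyr::left_join(
    tset$exons,
    dplyr::select(tset$transcripts, "transcript_id", "gene_id"),
    by = "transcript_id")
  out <- dplyr::summarise(
    dplyr::group_by(src, dplyr::across(dplyr::all_of(by))),
    chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
    strand = .data$strand[1], .groups = "drop")
  if (by == "transcript_id") {
    names(out)[1] <- "transcript_id"
  }
  out
}
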