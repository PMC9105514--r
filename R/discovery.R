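#' Novel-lncRNA filter cascade
#'
#' Applies the five discovery filters in order: (1) class code in
#' `i`, `j`, `o`, `u`, `x`; (2) length >= 200 nt; (3) all three
#' coding-potential tools call the transcript noncoding; (4) no
#' protein/ncRNA database hit; (5) FPKM >= 0.5 in at least one sample
#' (>= 2.0 for single-exon transcripts). Attrition is recorded per stage.
#'
#' @param candidates A [transcript_set] of assembled candidate transcripts.
#' @param coding_potential Tibble with `transcript_id`, the three tool
#'   verdicts `cnci`, `feelnc`, `cpc2` (each `"coding"`/`"noncoding"`) and a
#'   logical `db_hit`.
#' @param fpkm Matrix or tibble of FPKM values; rows named by (or a
#'   `transcript_id` column giving) transcript, one column per sample.
#' @param config A [run_config].
#' @return A list with `novel` (the surviving [transcript_set]) and `report`
#'   (tibble of `stage`, `n_in`, `n_out`, `n_removed`).
#' @export
filter_cascade <- function(candidates, coding_potential, fpkm,
                           config = run_config()) {
  tx <- candidates$transcripts
  if (is.data.frame(fpkm)) {
    fpkm_mat <- as.matrix(fpkm[setdiff(names(fpkm), "transcript_id")])
    rownames(fpkm_mat) <- fpkm$transcript_id
  } else {
    fpkm_mat <- fpkm
  }
  missing_cp <- setdiff(tx$transcript_id, coding_potential$transcript_id)
  missing_fpkm <- setdiff(tx$transcript_id, rownames(fpkm_mat))
  if (length(missing_cp) > 0 || length(missing_fpkm) > 0) {
    stop("candidates missing coding-potential or FPKM records: ",
         paste(utils::head(unique(c(missing_cp, missing_fpkm)), 10), collapse = ", "))
  }
  cp <- coding_potential[match(tx$transcript_id, coding_potential$transcript_id), ]
  max_fpkm <- apply(fpkm_mat[tx$transcript_id, , drop = FALSE], 1, max)

  stages <- list(
    class_code = tx$class_code %in% c("i", "j", "o", "u", "x"),
    length = tx$length >= config$min_length_nt,
    coding_potential = cp$cnci == "noncoding" & cp$feelnc == "noncoding" &
      cp$cpc2 == "noncoding",
    db_hit = !cp$db_hit,
    fpkm = ifelse(tx$n_exons == 1,
                  max_fpkm >= config$fpkm_min_single_exon,
                  max_fpkm >= config$fpkm_min)
  )
  keep <- rep(TRUE, nrow(tx))
  report <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    n_in <- sum(keep)
    keep_new <- keep & stages[[s]]
    report[[s]] <- tibble::tibble(
      stage = names(stages)[s], n_in = n_in, n_out = sum(keep_new),
      n_removed = n_in - sum(keep_new)
    )
    keep <- keep_new
  }
  report <- dplyr::bind_rows(report)
  novel <- subset_transcripts(candidates, tx$transcript_id[keep])
  novel$transcripts$biotype <- "candidate"
  log_stage("filter_cascade", nrow(tx), sum(keep), config)
  list(novel = novel, report = report)
}

#' Positional classification of lncRNAs
#'
#' Assigns each lncRNA exactly one of four positional classes relative to the
#' coding annotation, with precedence exonic > antisense > intronic >
#' lincRNA: `exonic` if any lncRNA exon overlaps a coding exon on the same
#' strand, `antisense` if the overlap is on the opposite strand, `intronic`
#' if the lncRNA lies within a coding gene span without exon overlap, and
#' `lincRNA` (intergenic) otherwise.
#'
#' @param lncrna A [transcript_set] of lncRNAs.
#' @param coding A [transcript_set] of protein-coding transcripts.
#' @return A tibble with `transcript_id` and `position_class`.
#' @export
classify_lncrna <- function(lncrna, coding) {
  lx <- intervals_to_granges(lncrna$exons)
  cx <- intervals_to_granges(coding$exons)
  # gene spans of coding transcripts
  ct <- dplyr::summarise(
    dplyr::group_by(coding$exons, .data$transcript_id),
    chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
    strand = .data$strand[1], .groups = "drop")
  cspan <- intervals_to_granges(ct)

  ids <- lncrna$transcripts$transcript_id
  res <- rep("lincRNA", length(ids))

  hits <- GenomicRanges::findOverlaps(lx, cx, ignore.strand = TRUE)
  if (length(hits) > 0) {
    same <- as.character(BiocGenerics::strand(lx))[S4Vectors::queryHits(hits)] ==
      as.character(BiocGenerics::strand(cx))[S4Vectors::subjectHits(hits)]
    ex_tid <- lncrna$exons$transcript_id[S4Vectors::queryHits(hits)]
    exonic_ids <- unique(ex_tid[same])
    anti_ids <- setdiff(unique(ex_tid[!same]), exonic_ids)
    res[ids %in% anti_ids] <- "antisense"
    res[ids %in% exonic_ids] <- "exonic"
  }

  # intronic: lncRNA span within a coding gene span, no exon overlap
  lt <- dplyr::summarise(
    dplyr::group_by(lncrna$exons, .data$transcript_id),
    chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
    strand = .data$strand[1], .groups = "drop")
  lspan <- intervals_to_granges(lt)
  within <- GenomicRanges::findOverlaps(lspan, cspan, type = "within",
                                        ignore.strand = TRUE)
  within_ids <- unique(lt$transcript_id[S4Vectors::queryHits(within)])
  res[ids %in% within_ids & res == "lincRNA"] <- "intronic"

  tibble::tibble(transcript_id = ids, position_class = res)
}

#' Length of the longest open reading frame
#'
#' Scans the three forward frames of the given sense-strand sequence for the
#' longest `ATG`..stop open reading frame. The returned length includes the
#' stop codon; 0 if no complete ORF exists.
#'
#' @param sequence A nucleotide string over `A`, `C`, `G`, `T`/`U`, `N`
#'   (case-insensitive).
#' @return Integer ORF length in nucleotides.
#' @export
longest_orf <- function(sequence) {
  s <- toupper(sequence)
  s <- gsub("U", "T", s, fixed = TRUE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence contains non-IUPAC characters: ",
         paste(unique(chars[!chars %in% c("A", "C", "G", "T", "N")]), collapse = ""))
  }
  n <- length(chars)
  best <- 0L
  for (frame in 0:2) {
    idx <- seq(frame + 1, n - 2, by = 3)
    if (length(idx) == 0 || idx[1] > n - 2) next
    codons <- paste0(chars[idx], chars[idx + 1], chars[idx + 2])
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(starts) == 0 || length(stops) == 0) next
    # first stop at or after each start
    pos <- findInterval(starts - 1L, stops) + 1L
    ok <- pos <= length(stops)
    if (!any(ok)) next
    lens <- (stops[pos[ok]] - starts[ok] + 1L) * 3L
    best <- max(best, max(lens))
  }
  best
}

#' Summarize the lncRNA catalog
#'
#' Combines novel and annotated lncRNAs into the expressed lncRNA universe
#' and tabulates positional-class proportions and structural statistics.
#'
#' @param novel A [transcript_set] of novel lncRNAs.
#' @param annotated A [transcript_set] of annotated lncRNAs (disjoint ids).
#' @param classes Optional tibble from [classify_lncrna] for the novel set.
#' @return A list with `n_novel`, `n_annotated`, `n_expressed`,
#'   `class_table` (count and percentage per positional class, percentages
#'   rounded to 2 decimals) and `structure` (length/exon summaries).
#' @export
summarize_catalog <- function(novel, annotated, classes = NULL) {
  dup <- intersect(novel$transcripts$transcript_id,
                   annotated$transcripts$transcript_id)
  if (length(dup) > 0) {
    stop("duplicate transcript id(s) across sets: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  n_novel <- nrow(novel$transcripts)
  n_annotated <- nrow(annotated$transcripts)
  class_table <- tibble::tibble(position_class = character(),
                                n = integer(), percent = numeric())
  if (!is.null(classes) && nrow(classes) > 0) {
    class_table <- dplyr::count(classes, .data$position_class, name = "n")
    class_table$percent <- round(100 * class_table$n / sum(class_table$n), 2)
  }
  structure_tbl <- dplyr::bind_rows(
    dplyr::mutate(novel$transcripts, set = "novel"),
    dplyr::mutate(annotated$transcripts, set = "annotated")
  )
  structure_tbl <- dplyr::summarise(
    dplyr::group_by(structure_tbl, .data$set),
    n = dplyr::n(),
    median_length = stats::median(.data$length),
    median_exons = stats::median(.data$n_exons),
    .groups = "drop"
  )
  list(n_novel = n_novel, n_annotated = n_annotated,
       n_expressed = n_novel + n_annotated,
       class_table = class_table, structure = structure_tbl)
}
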