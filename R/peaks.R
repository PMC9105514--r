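#' Window-based m6A peak calling
#'
#' A simplified enrichment caller over spliced-transcript coordinates. Input
#' is a per-transcript track of 50-nt bin counts (IP and Input); sliding
#' 100-nt windows (step 50) are formed by summing adjacent bins. Each window
#' is tested for IP enrichment against the rest of the transcript with a
#' one-sided Fisher exact test (hypergeometric upper tail on the 2x2 table
#' window/rest x IP/Input), p-values are BH-adjusted across all windows, and
#' adjacent or overlapping significant windows are merged into peaks. The
#' summit is the center of the merged window with the highest IP/Input ratio.
#'
#' @param bins Tibble with `transcript_id`, `bin_start`, `bin_end`, `ip`,
#'   `input` (and optionally `tissue`, carried through); bins are
#'   consecutive 50-nt intervals in transcript coordinates.
#' @param config A [run_config]; `peak_window_nt`, `peak_step_nt` and
#'   `peak_padj` are used.
#' @return A tibble of peaks: `transcript_id` (+ `tissue` if present),
#'   `start`, `end`, `summit` (transcript coordinates), `ip_count`,
#'   `input_count`, `pvalue`, `padj`.
#' @export
call_peaks <- function(bins, config = run_config()) {
  group_cols <- intersect(c("transcript_id", "tissue"), names(bins))
  bins <- dplyr::arrange(bins, dplyr::across(dplyr::all_of(group_cols)),
                         .data$bin_start)
  per_bin <- as.integer(config$peak_step_nt)
  bins_per_win <- max(1L, as.integer(round(config$peak_window_nt / per_bin)))

  make_windows <- function(df) {
    n <- nrow(df)
    n_win <- max(1L, n - bins_per_win + 1L)
    idx <- seq_len(n_win)
    ip_w <- vapply(idx, function(i) sum(df$ip[i:min(n, i + bins_per_win - 1L)]), 0)
    in_w <- vapply(idx, function(i) sum(df$input[i:min(n, i + bins_per_win - 1L)]), 0)
    tibble::tibble(
      start = df$bin_start[idx],
      end = df$bin_end[pmin(n, idx + bins_per_win - 1L)],
      ip = ip_w, input = in_w,
      ip_total = sum(df$ip), input_total = sum(df$input)
    )
  }
  win <- dplyr::reframe(dplyr::group_by(bins, dplyr::across(dplyr::all_of(group_cols))),
                        make_windows(dplyr::pick(dplyr::everything())))
  # a transcript shorter than one window has no within-transcript background;
  # test its single whole-transcript window against the library-wide totals
  single <- win$ip == win$ip_total & win$input == win$input_total
  if (any(single)) {
    if ("tissue" %in% names(win)) {
      g_ip <- tapply(bins$ip, bins$tissue, sum)[win$tissue]
      g_in <- tapply(bins$input, bins$tissue, sum)[win$tissue]
      win$ip_total[single] <- g_ip[single]
      win$input_total[single] <- g_in[single]
    } else {
      win$ip_total[single] <- sum(bins$ip)
      win$input_total[single] <- sum(bins$input)
    }
  }
  # one-sided Fisher exact p via the hypergeometric upper tail
  win$pvalue <- stats::phyper(win$ip - 1, win$ip_total,
                              win$input_total, win$ip + win$input,
                              lower.tail = FALSE)
  win$pvalue[win$ip_total == 0 | win$input_total == 0] <- 1
  win$padj <- benjamini_hochberg(win$pvalue)
  sig <- win[!is.na(win$padj) & win$padj < config$peak_padj, , drop = FALSE]
  if (nrow(sig) == 0) {
    out <- sig[, group_cols, drop = FALSE]
    out$start <- numeric(0); out$end <- numeric(0); out$summit <- numeric(0)
    out$ip_count <- numeric(0); out$input_count <- numeric(0)
    out$pvalue <- numeric(0); out$padj <- numeric(0)
    return(tibble::as_tibble(out))
  }
  sig$ratio <- (sig$ip + 0.5) / (sig$input + 0.5)
  merge_group <- function(df) {
    df <- df[order(df$start), , drop = FALSE]
    df$block <- cumsum(c(TRUE, df$start[-1] > cummax(df$end)[-nrow(df)]))
    out <- dplyr::summarise(
      dplyr::group_by(df, .data$block),
      summit = floor((.data$start[which.max(.data$ratio)] +
                        .data$end[which.max(.data$ratio)]) / 2),
      start = min(.data$start), end = max(.data$end),
      ip_count = max(.data$ip), input_count = max(.data$input),
      pvalue = min(.data$pvalue), padj = min(.data$padj),
      .groups = "drop"
    )
    out[, c("start", "end", "summit", "ip_count", "input_count",
            "pvalue", "padj")]
  }
  peaks <- dplyr::reframe(dplyr::group_by(sig, dplyr::across(dplyr::all_of(group_cols))),
                          merge_group(dplyr::pick(dplyr::everything())))
  tibble::as_tibble(peaks)
}

#' Assign peaks to lncRNAs and label novelty
#'
#' A peak is assigned to an expressed lncRNA when its summit lies in an exon
#' of that lncRNA; a summit falling in two overlapping lncRNAs yields one
#' assignment per lncRNA with a warning. A peak is `known` when its interval
#' overlaps at least one known m6A site by >= 1 bp, otherwise `unknown`.
#'
#' @param peaks Tibble of peaks in genome coordinates: `chrom`, `start`,
#'   `end`, `summit` (0-based genomic) plus any extra columns.
#' @param lncrna A [transcript_set] of expressed lncRNAs.
#' @param known_sites Interval table of known m6A sites (may be empty).
#' @return `peaks` with `transcript_id` and `novelty` columns (peaks whose
#'   summit hits no lncRNA exon are dropped).
#' @export
assign_and_label <- function(peaks, lncrna, known_sites = NULL) {
  if (nrow(peaks) == 0) {
    peaks$transcript_id <- character(0)
    peaks$novelty <- character(0)
    return(peaks)
  }
  summit_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$summit + 1, peaks$summit + 1))
  ex_gr <- intervals_to_granges(lncrna$exons)
  hits <- GenomicRanges::findOverlaps(summit_gr, ex_gr, ignore.strand = TRUE)
  assigned <- tibble::tibble(
    peak_row = S4Vectors::queryHits(hits),
    transcript_id = lncrna$exons$transcript_id[S4Vectors::subjectHits(hits)]
  )
  assigned <- dplyr::distinct(assigned)
  multi <- dplyr::count(assigned, .data$peak_row)
  if (any(multi$n > 1)) {
    warning(sum(multi$n > 1), " peak summit(s) assigned to multiple ",
            "overlapping lncRNAs")
  }
  out <- dplyr::bind_cols(peaks[assigned$peak_row, , drop = FALSE],
                          assigned["transcript_id"])
  out$novelty <- "unknown"
  if (!is.null(known_sites) && nrow(known_sites) > 0) {
    pk_gr <- GenomicRanges::GRanges(
      out$chrom, IRanges::IRanges(out$start + 1, out$end))
    ks_gr <- intervals_to_granges(known_sites)
    ov <- GenomicRanges::findOverlaps(pk_gr, ks_gr, ignore.strand = TRUE)
    out$novelty[unique(S4Vectors::queryHits(ov))] <- "known"
  }
  tibble::as_tibble(out)
}

#' MeRIP enrichment (MFPKM) per transcript
#'
#' Per-replicate IP/Input FPKM ratios with an Input floor; the MFPKM is the
#' mean of the ratios over replicates and the m6A level its log2. Replicates
#' whose Input FPKM is below the floor are dropped; a transcript with no
#' usable replicate gets an `NA` record.
#'
#' @param fpkm_ip,fpkm_input FPKM matrices, transcripts x replicates, with
#'   matching dimensions and rownames.
#' @param input_floor Minimum Input FPKM for a usable replicate.
#' @return Tibble with `transcript_id`, `mfpkm`, `m6a_level`, `n_replicates`.
#' @export
mfpkm <- function(fpkm_ip, fpkm_input, input_floor = 0.5) {
  fpkm_ip <- as.matrix(fpkm_ip)
  fpkm_input <- as.matrix(fpkm_input)
  stopifnot(all(dim(fpkm_ip) == dim(fpkm_input)))
  ratio <- fpkm_ip / fpkm_input
  ratio[fpkm_input < input_floor] <- NA
  n_ok <- rowSums(!is.na(ratio))
  mf <- rowMeans(ratio, na.rm = TRUE)
  mf[n_ok == 0] <- NA
  tibble::tibble(
    transcript_id = rownames(fpkm_ip),
    mfpkm = as.numeric(mf),
    m6a_level = log2(as.numeric(mf)),
    n_replicates = as.integer(n_ok)
  )
}

#' Metagene profile of peak summits
#'
#' Maps each peak summit to its spliced-transcript coordinate (already
#' 5'-to-3' on the sense strand, so the profile is strand-invariant), scales
#' the transcript body to `[0, 1]` over `n_bins` bins with fixed-width
#' flanking panels of `flank_bp` on each side, and reports the normalized
#' density plus the (first, internal, last) exon fractions of summits over
#' multi-exon transcripts.
#'
#' @param peaks Tibble with `transcript_id` and `summit` in
#'   spliced-transcript coordinates (e.g. from [call_peaks]).
#' @param transcripts A [transcript_set] covering the peak transcripts.
#' @param n_bins Number of body bins.
#' @param flank_bp Width of each flanking panel in bp.
#' @return A list with `profile` (tibble `bin`, `region`, `position`,
#'   `density`; densities sum to 1), `exon_fractions` (named vector summing
#'   to 1 over multi-exon transcripts) and `last_exon_fraction`.
#' @export
metagene_profile <- function(peaks, transcripts, n_bins = 100, flank_bp = 1000) {
  tx <- transcripts$transcripts
  lens <- stats::setNames(tx$length, tx$transcript_id)
  unknown <- setdiff(peaks$transcript_id, names(lens))
  if (length(unknown) > 0) {
    stop("peaks assigned to unknown transcripts: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  pos <- peaks$summit
  len <- lens[peaks$transcript_id]
  if (any(pos < 0 | pos >= len)) {
    stop("peak summit outside its assigned transcript")
  }
  rel <- pos / len

  n_flank_bins <- max(1L, round(n_bins / 5))
  body_bin <- pmin(n_bins, floor(rel * n_bins) + 1L)
  counts <- tabulate(body_bin, nbins = n_bins)
  profile <- tibble::tibble(
    bin = seq_len(2 * n_flank_bins + n_bins),
    region = c(rep("flank5", n_flank_bins), rep("body", n_bins),
               rep("flank3", n_flank_bins)),
    position = c(seq(-flank_bp, 0, length.out = n_flank_bins + 1)[-(n_flank_bins + 1)] / flank_bp,
                 seq(0, 1, length.out = n_bins + 1)[-(n_bins + 1)] + 0.5 / n_bins,
                 1 + seq(0, flank_bp, length.out = n_flank_bins + 1)[-1] / flank_bp),
    density = c(rep(0, n_flank_bins), counts / sum(counts), rep(0, n_flank_bins))
  )

  # exon position of each summit (multi-exon transcripts only)
  ex <- transcripts$exons
  n_ex <- stats::setNames(tx$n_exons, tx$transcript_id)
  multi <- n_ex[peaks$transcript_id] > 1
  exon_fractions <- c(first = NA_real_, internal = NA_real_, last = NA_real_)
  last_exon_fraction <- NA_real_
  if (any(multi)) {
    ex_split <- split(ex, ex$transcript_id)
    which_exon <- function(tid, p) {
      exi <- ex_split[[tid]]
      exi <- exi[order(exi$start), , drop = FALSE]
      w <- exi$end - exi$start
      if (exi$strand[1] == "-") w <- rev(w)
      findInterval(p, cumsum(w)) + 1L # 1-based exon index in 5'->3' order
    }
    ei <- mapply(which_exon, peaks$transcript_id[multi], pos[multi])
    ne <- n_ex[peaks$transcript_id[multi]]
    cat3 <- ifelse(ei == 1, "first", ifelse(ei == ne, "last", "internal"))
    tb <- table(factor(cat3, levels = c("first", "internal", "last")))
    exon_fractions <- as.numeric(tb) / sum(tb)
    names(exon_fractions) <- c("first", "internal", "last")
    last_exon_fraction <- exon_fractions[["last"]]
  }
  list(profile = profile, exon_fractions = exon_fractions,
       last_exon_fraction = last_exon_fraction)
}

iupac_codes <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Test sequences for an IUPAC consensus motif
#'
#' @param sequences Character vector of DNA/RNA sequences (U is read as T).
#' @param consensus IUPAC consensus string (e.g. `"RRACH"`), up to `max_len`.
#' @param max_len Maximum consensus length accepted.
#' @return Logical vector: does each sequence contain >= 1 match?
#' @export
has_motif <- function(sequences, consensus, max_len = 8) {
  consensus <- toupper(gsub("U", "T", consensus, fixed = TRUE))
  cs <- strsplit(consensus, "")[[1]]
  if (any(!cs %in% names(iupac_codes))) {
    stop("invalid IUPAC code in consensus: ",
         paste(unique(cs[!cs %in% names(iupac_codes)]), collapse = ""))
  }
  if (length(cs) > max_len) stop("consensus longer than ", max_len, " bp")
  seqs <- Biostrings::DNAStringSet(toupper(gsub("U", "T", sequences, fixed = TRUE)))
  Biostrings::vcountPattern(consensus, seqs, fixed = FALSE) > 0
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles each sequence while preserving its exact dinucleotide counts
#' (Altschul-Erickson Eulerian-path shuffle): the dinucleotide transition
#' multigraph is walked along a random Eulerian path anchored by a random
#' last-edge tree into the final nucleotide.
#'
#' @param sequences Character vector of sequences.
#' @return Character vector of shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequences) {
  vapply(sequences, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n < 3) return(s)
    from <- chars[-n]
    to <- chars[-1]
    verts <- unique(chars)
    last <- chars[n]
    edges <- split(to, factor(from, levels = verts))
    for (attempt in seq_len(200)) {
      # pick a random terminal edge for every vertex except the last
      last_edge <- vapply(verts, function(v) {
        if (v == last || length(edges[[v]]) == 0) return(NA_character_)
        sample(edges[[v]], 1)
      }, "")
      # the terminal edges must form a tree pointing into `last`
      ok <- TRUE
      for (v in verts) {
        if (v == last || is.na(last_edge[[v]])) next
        seen <- character(0)
        cur <- v
        while (cur != last) {
          if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- last_edge[[cur]]
        }
        if (!ok) break
      }
      if (ok) break
    }
    if (!ok) return(s) # degenerate composition; leave unshuffled
    shuffled <- lapply(verts, function(v) {
      e <- edges[[v]]
      if (!is.na(last_edge[[v]]) && v != last) {
        drop_at <- match(last_edge[[v]], e)
        e <- e[-drop_at]
      }
      e <- if (length(e) > 1) sample(e) else e
      if (v != last && !is.na(last_edge[[v]])) c(e, last_edge[[v]]) else e
    })
    names(shuffled) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1] <- chars[1]
    cur <- chars[1]
    for (i in 2:n) {
      nxt <- shuffled[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Consensus-motif enrichment in peak sequences
#'
#' Tests whether target (peak) sequences contain a consensus motif more often
#' than background sequences using a one-sided Fisher exact test on per-
#' sequence presence/absence. By default the background is a dinucleotide-
#' preserving shuffle of the targets.
#'
#' @param target_sequences Character vector of peak sequences.
#' @param consensus IUPAC consensus motif, up to `max_len` bases.
#' @param background_sequences Optional explicit background; defaults to
#'   [dinucleotide_shuffle] of the targets.
#' @param max_len Maximum consensus length.
#' @return A list with `odds_ratio`, `pvalue`, `target_hits`, `background_hits`,
#'   `n_target`, `n_background`.
#' @export
motif_enrichment <- function(target_sequences, consensus,
                             background_sequences = NULL, max_len = 8) {
  if (is.null(background_sequences)) {
    background_sequences <- dinucleotide_shuffle(target_sequences)
  }
  t_hit <- sum(has_motif(target_sequences, consensus, max_len))
  b_hit <- sum(has_motif(background_sequences, consensus, max_len))
  nt <- length(target_sequences)
  nb <- length(background_sequences)
  tab <- matrix(c(t_hit, nt - t_hit, b_hit, nb - b_hit), nrow = 2)
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), pvalue = ft$p.value,
       target_hits = t_hit, background_hits = b_hit,
       n_target = nt, n_background = nb)
}

#' Extract transcript (spliced) sequences from a genome
#'
#' Strand-aware: minus-strand transcripts are reverse complemented so the
#' returned sequence reads 5' to 3'.
#'
#' @param tset A [transcript_set].
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @return Named character vector of transcript sequences.
#' @export
transcript_sequences <- function(tset, genome) {
  ex_split <- split(tset$exons, tset$exons$transcript_id)
  vapply(ex_split, function(exi) {
    exi <- exi[order(exi$start), , drop = FALSE]
    parts <- vapply(seq_len(nrow(exi)), function(k) {
      as.character(Biostrings::subseq(genome[[exi$chrom[1]]],
                                      start = exi$start[k] + 1,
                                      end = exi$end[k]))
    }, "")
    s <- paste(parts, collapse = "")
    if (exi$strand[1] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, "")
}

#' Extract sequence windows around peak summits
#'
#' @param peaks Tibble with `transcript_id` and `summit` (transcript
#'   coordinates).
#' @param tset A [transcript_set].
#' @param genome A [Biostrings::DNAStringSet].
#' @param half_width Half-width of the window around the summit.
#' @return Character vector of peak sequences (sense strand).
#' @export
peak_sequences <- function(peaks, tset, genome, half_width = 50) {
  seqs <- transcript_sequences(subset_transcripts(tset, unique(peaks$transcript_id)),
                               genome)
  vapply(seq_len(nrow(peaks)), function(i) {
    s <- seqs[[peaks$transcript_id[i]]]
    lo <- max(1, peaks$summit[i] + 1 - half_width)
    hi <- min(nchar(s), peaks$summit[i] + 1 + half_width)
    substr(s, lo, hi)
  }, "")
}
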