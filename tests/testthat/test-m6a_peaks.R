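uniform_bins <- function(id, len, ip, input, tissue = NULL) {
  n <- len / 50
  out <- tibble::tibble(transcript_id = id,
                        bin_start = (seq_len(n) - 1) * 50,
                        bin_end = seq_len(n) * 50,
                        ip = ip, input = input)
  if (!is.null(tissue)) out$tissue <- tissue
  out
}

test_that("an enriched window is called and its p matches fisher.test", {
  bins <- uniform_bins("t1", 1000, ip = 5, input = 5)
  bins$ip[7] <- 120 # strong elevation at [300,350)
  pk <- call_peaks(bins)
  expect_equal(nrow(pk), 1)
  expect_true(pk$start <= 300 && pk$end >= 350)
  expect_true(pk$summit >= pk$start && pk$summit < pk$end)

  # oracle: one-sided Fisher on the best window vs the rest of the transcript
  ip_tot <- sum(bins$ip)
  in_tot <- sum(bins$input)
  ip_w <- sum(bins$ip[6:7]) # the [250,350) window containing the spike
  in_w <- sum(bins$input[6:7])
  oracle <- fisher.test(matrix(c(ip_w, ip_tot - ip_w, in_w, in_tot - in_w),
                               nrow = 2), alternative = "greater")$p.value
  expect_equal(pk$pvalue, oracle, tolerance = 1e-12)
})

test_that("an IP track proportional to Input yields no peaks", {
  bins <- uniform_bins("t1", 1000, ip = 40, input = 20)
  pk <- call_peaks(bins)
  expect_equal(nrow(pk), 0)
})

test_that("adjacent significant windows merge into one peak", {
  bins <- uniform_bins("t1", 1000, ip = 2, input = 10)
  bins$ip[7:10] <- 200 # plateau spanning several overlapping windows
  pk <- call_peaks(bins)
  expect_equal(nrow(pk), 1)
  expect_lte(pk$start, 300)
  expect_gte(pk$end, 500)
})

test_that("a transcript shorter than one window is tested whole", {
  bins <- tibble::tibble(transcript_id = "tiny", bin_start = 0, bin_end = 80,
                         ip = 50, input = 5)
  pk <- call_peaks(dplyr::bind_rows(
    bins, uniform_bins("other", 1000, ip = 100, input = 100)))
  expect_true("tiny" %in% pk$transcript_id)
})

test_that("MFPKM follows the stated arithmetic with the Input floor", {
  ip <- matrix(c(10, 5, 4, 10, 5, 4), nrow = 2, byrow = TRUE,
               dimnames = list(c("x", "y"), paste0("r", 1:3)))
  input <- matrix(c(5, 5, 5, 10, 5, 4), nrow = 2, byrow = TRUE,
                  dimnames = dimnames(ip))
  got <- mfpkm(ip, input)
  expect_equal(got$mfpkm[got$transcript_id == "x"], mean(c(2, 1, 4 / 5)))
  expect_equal(got$m6a_level[got$transcript_id == "y"], 0) # identical tracks

  ratios <- mfpkm(matrix(c(1, 2, 4), 1, dimnames = list("z", NULL)),
                  matrix(c(1, 1, 1), 1, dimnames = list("z", NULL)))
  expect_equal(ratios$mfpkm, 7 / 3)

  low <- mfpkm(matrix(5, 1, 3, dimnames = list("w", NULL)),
               matrix(0.2, 1, 3, dimnames = list("w", NULL)))
  expect_true(is.na(low$mfpkm))
  expect_equal(low$n_replicates, 0L)
})

test_that("summit assignment and novelty labeling follow the overlap rules", {
  tset <- toy_tset()
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(40, 340, 600),
                          end = c(80, 380, 640),
                          summit = c(60, 360, 620))
  got <- assign_and_label(peaks, tset, known_sites = NULL)
  # summit 620 is in no exon -> dropped
  expect_equal(nrow(got), 2)
  expect_true(all(got$transcript_id == "txA"))
  expect_true(all(got$novelty == "unknown"))

  # a 1-bp interval overlap with a known site suffices
  known <- genomic_intervals("chr1", 79, 120, "+")
  known$site_id <- "s1"
  got2 <- assign_and_label(peaks, tset, known)
  expect_equal(got2$novelty[got2$summit == 60], "known")
  expect_equal(got2$novelty[got2$summit == 360], "unknown")

  # overlapping lncRNAs: both assignments, with a warning
  twin <- tset
  twin$transcripts <- dplyr::bind_rows(
    twin$transcripts,
    dplyr::mutate(twin$transcripts[1, ], transcript_id = "txA2", gene_id = "gA2"))
  twin$exons <- dplyr::bind_rows(
    twin$exons,
    dplyr::mutate(twin$exons[twin$exons$transcript_id == "txA", ],
                  transcript_id = "txA2"))
  expect_warning(got3 <- assign_and_label(peaks, twin, NULL), "multiple")
  expect_equal(sum(got3$summit == 60), 2)
})

test_that("transcript/genome coordinate maps are mutually inverse and strand-aware", {
  tset <- toy_tset()
  # txB is minus strand, exons [1000,1150) + [1500,1600); transcript pos 0 is
  # the 3'-most genomic base (1599)
  gen <- transcript_coords_to_genome("txB", 0, tset)
  expect_equal(gen$pos, 1599)
  expect_equal(gen$strand, "-")
  back <- genome_coords_to_transcript("txB", 1599, tset)
  expect_equal(back, 0)
  set.seed(4)
  for (p in sample(0:249, 20)) {
    g <- transcript_coords_to_genome("txB", p, tset)
    expect_equal(genome_coords_to_transcript("txB", g$pos, tset), p)
  }
  expect_error(transcript_coords_to_genome("txA", 200, tset), "outside")
})

test_that("the metagene profile normalizes, localizes and respects contracts", {
  one <- transcript_set(
    tibble::tibble(transcript_id = "s", gene_id = "s", chrom = "chr1",
                   strand = "+", class_code = "u", biotype = "candidate",
                   n_exons = 1L, length = 1000),
    tibble::tibble(transcript_id = "s", chrom = "chr1", start = 0, end = 1000,
                   strand = "+", exon_rank = 1L))
  prof <- metagene_profile(tibble::tibble(transcript_id = "s", summit = 500), one)
  expect_equal(sum(prof$profile$density), 1)
  hot <- prof$profile$bin[which.max(prof$profile$density)]
  expect_equal(prof$profile$region[hot], "body")
  expect_equal(prof$profile$position[hot], 0.505, tolerance = 0.01)

  expect_error(
    metagene_profile(tibble::tibble(transcript_id = "s", summit = 1500), one),
    "outside")
  expect_error(
    metagene_profile(tibble::tibble(transcript_id = "nope", summit = 1), one),
    "unknown")
})

test_that("uniform planting yields a flat profile (chi-square goodness of fit)", {
  set.seed(9)
  one <- transcript_set(
    tibble::tibble(transcript_id = "s", gene_id = "s", chrom = "chr1",
                   strand = "+", class_code = "u", biotype = "candidate",
                   n_exons = 1L, length = 10000),
    tibble::tibble(transcript_id = "s", chrom = "chr1", start = 0, end = 10000,
                   strand = "+", exon_rank = 1L))
  peaks <- tibble::tibble(transcript_id = "s",
                          summit = sample(0:9999, 5000, replace = TRUE))
  prof <- metagene_profile(peaks, one, n_bins = 20)
  counts <- prof$profile$density[prof$profile$region == "body"] * 5000
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("IUPAC motif matching expands degenerate codes", {
  expect_true(has_motif("GGACU", "RRACH"))
  expect_true(has_motif("ggact", "rrach"))
  expect_false(has_motif("CCCCC", "RRACH"))
  expect_error(has_motif("ACGT", "RRZCH"), "invalid IUPAC")
  expect_error(has_motif("ACGT", "AAAAAAAAA"), "longer than 8")
})

test_that("dinucleotide shuffling preserves dinucleotide composition", {
  set.seed(13)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(sort(as.vector(dinuc_counts(sh))), sort(as.vector(dinuc_counts(s))))
    expect_identical(names(dinuc_counts(sh)), names(dinuc_counts(s)))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  }
})

test_that("planted motifs are enriched against a shuffled background", {
  set.seed(17)
  seqs <- vapply(1:200, function(i) {
    s <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
    if (runif(1) < 0.9) {
      at <- sample(1:96, 1)
      s[at:(at + 4)] <- c("G", "G", "A", "C", "A")
    }
    paste(s, collapse = "")
  }, "")
  res <- motif_enrichment(seqs, "RRACH")
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$pvalue, 0.01)
})

test_that("peak and transcript sequences are extracted strand-aware", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 500), collapse = "")))
  tset <- toy_tset()
  seqs <- transcript_sequences(tset, genome)
  expect_equal(nchar(seqs[["txA"]]), 200)
  expect_equal(nchar(seqs[["txB"]]), 250)
  # txB minus strand: its transcript sequence is the reverse complement of
  # the concatenated genomic exons
  fwd <- paste0(substr(as.character(genome[[1]]), 1001, 1150),
                substr(as.character(genome[[1]]), 1501, 1600))
  expect_equal(seqs[["txB"]],
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd))))
  pk <- peak_sequences(tibble::tibble(transcript_id = "txA", summit = 100),
                       tset, genome, half_width = 10)
  expect_equal(nchar(pk), 21)
})
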