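make_candidates <- function(rows, exons) {
  transcript_set(rows, exons)
}

test_that("cascade filters apply in order with the stated thresholds", {
  rows <- tibble::tibble(
    transcript_id = paste0("t", 1:5),
    gene_id = paste0("g", 1:5),
    chrom = "chr1", strand = "+",
    class_code = c("=", "u", "u", "u", "u"),
    biotype = "candidate",
    n_exons = c(2L, 1L, 2L, 1L, 2L),
    length = c(5000, 150, 1000, 1000, 1000)
  )
  exons <- tibble::tibble(
    transcript_id = rep(rows$transcript_id, rows$n_exons),
    chrom = "chr1", strand = "+", start = 0, end = 1, exon_rank = 1L
  )
  cp <- tibble::tibble(transcript_id = rows$transcript_id,
                       cnci = "noncoding", feelnc = "noncoding",
                       cpc2 = "noncoding", db_hit = FALSE)
  fpkm <- matrix(c(10, 10, 10, 1.0, 0.6), ncol = 1,
                 dimnames = list(rows$transcript_id, "s1"))
  res <- suppressMessages(filter_cascade(make_candidates(rows, exons), cp, fpkm))
  # t1: class "=" out at stage 1 despite length/noncoding
  # t2: class u but 150 nt, out at stage 2
  # t4: single-exon with max FPKM 1.0 < 2.0, out at stage 5
  # t5: multi-exon with max FPKM 0.6 >= 0.5, retained
  expect_setequal(res$novel$transcripts$transcript_id, c("t3", "t5"))
  expect_equal(res$report$n_removed, c(1, 1, 0, 0, 1))
  expect_equal(res$report$n_in[-1], res$report$n_out[-nrow(res$report)])
})

test_that("coding-potential and database filters require all-noncoding, no hit", {
  rows <- tibble::tibble(
    transcript_id = c("a", "b", "c"), gene_id = c("a", "b", "c"),
    chrom = "chr1", strand = "+", class_code = "u", biotype = "candidate",
    n_exons = 2L, length = 1000
  )
  exons <- tibble::tibble(transcript_id = rep(rows$transcript_id, 2),
                          chrom = "chr1", strand = "+", start = 0, end = 1,
                          exon_rank = 1L)
  cp <- tibble::tibble(
    transcript_id = c("a", "b", "c"),
    cnci = c("noncoding", "coding", "noncoding"),
    feelnc = "noncoding", cpc2 = "noncoding",
    db_hit = c(FALSE, FALSE, TRUE)
  )
  fpkm <- matrix(10, nrow = 3, ncol = 2,
                 dimnames = list(rows$transcript_id, c("s1", "s2")))
  res <- suppressMessages(filter_cascade(make_candidates(rows, exons), cp, fpkm))
  expect_equal(res$novel$transcripts$transcript_id, "a")
  expect_error(
    filter_cascade(make_candidates(rows, exons), cp[-1, ], fpkm),
    "missing"
  )
})

test_that("the cascade is idempotent", {
  study <- small_study()
  fp <- study$counts$fpkm_input
  cand_fp <- fp[intersect(rownames(fp),
                          study$annotation$assembled$transcripts$transcript_id), ,
                drop = FALSE]
  first <- suppressMessages(filter_cascade(
    study$annotation$assembled, study$context$coding_potential, cand_fp))
  second <- suppressMessages(filter_cascade(
    first$novel, study$context$coding_potential, cand_fp))
  expect_equal(second$report$n_removed, rep(0, 5))
  expect_identical(sort(second$novel$transcripts$transcript_id),
                   sort(first$novel$transcripts$transcript_id))
})

test_that("positional classification follows the exonic > antisense > intronic > lincRNA precedence", {
  coding <- transcript_set(
    tibble::tibble(transcript_id = "cg.t1", gene_id = "cg", chrom = "chr1",
                   strand = "+", class_code = "=", biotype = "coding",
                   n_exons = 2L, length = 200),
    tibble::tibble(transcript_id = "cg.t1", chrom = "chr1",
                   start = c(1000, 2000), end = c(1100, 2100), strand = "+",
                   exon_rank = 1:2)
  )
  lnc_rows <- tibble::tibble(
    transcript_id = c("ex_sense", "ex_anti", "intronic", "far"),
    gene_id = transcript_id, chrom = "chr1",
    strand = c("+", "-", "+", "+"),
    class_code = "u", biotype = "candidate", n_exons = 1L, length = 300
  )
  lnc_ex <- tibble::tibble(
    transcript_id = lnc_rows$transcript_id, chrom = "chr1",
    start = c(1050, 1050, 1300, 50000),
    end = c(1350, 1350, 1600, 50300),
    strand = lnc_rows$strand, exon_rank = 1L
  )
  got <- classify_lncrna(transcript_set(lnc_rows, lnc_ex), coding)
  expect_equal(got$position_class[got$transcript_id == "ex_sense"], "exonic")
  expect_equal(got$position_class[got$transcript_id == "ex_anti"], "antisense")
  expect_equal(got$position_class[got$transcript_id == "intronic"], "intronic")
  expect_equal(got$position_class[got$transcript_id == "far"], "lincRNA")
  # totality: exactly one label each
  expect_equal(nrow(got), 4)
  expect_true(all(got$position_class %in%
                    c("exonic", "antisense", "intronic", "lincRNA")))
})

test_that("every synthetic lncRNA receives exactly one positional label", {
  study <- small_study()
  coding <- subset_transcripts(
    study$annotation$reference,
    study$annotation$reference$transcripts$transcript_id[
      study$annotation$reference$transcripts$biotype == "coding"])
  got <- classify_lncrna(study$annotation$assembled, coding)
  expect_equal(nrow(got), nrow(study$annotation$assembled$transcripts))
  expect_false(any(is.na(got$position_class)))
})

test_that("longest_orf matches hand cases and the brute-force oracle", {
  expect_equal(longest_orf("ATGAAATAA"), 9)
  expect_equal(longest_orf("CCCCCC"), 0)
  expect_equal(longest_orf("atgaaataa"), 9) # case-insensitive
  expect_equal(longest_orf("AUGAAAUAA"), 9) # RNA alphabet
  expect_error(longest_orf("ATGXXX"), "non-IUPAC")

  set.seed(42)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    expect_equal(longest_orf(s), orf_oracle(s))
  }
})

test_that("catalog summary reproduces proportions and guards id collisions", {
  novel <- transcript_set(
    tibble::tibble(transcript_id = paste0("n", 1:3), gene_id = paste0("n", 1:3),
                   chrom = "chr1", strand = "+", class_code = "u",
                   biotype = "candidate", n_exons = 1L, length = 500),
    tibble::tibble(transcript_id = paste0("n", 1:3), chrom = "chr1", start = 0,
                   end = 500, strand = "+", exon_rank = 1L))
  annotated <- transcript_set(
    tibble::tibble(transcript_id = paste0("a", 1:2), gene_id = paste0("a", 1:2),
                   chrom = "chr1", strand = "+", class_code = "=",
                   biotype = "annotated_lncRNA", n_exons = 1L, length = 500),
    tibble::tibble(transcript_id = paste0("a", 1:2), chrom = "chr1", start = 0,
                   end = 500, strand = "+", exon_rank = 1L))
  classes <- tibble::tibble(
    transcript_id = paste0("n", 1:3),
    position_class = c("intronic", "intronic", "lincRNA"))
  got <- summarize_catalog(novel, annotated, classes)
  expect_equal(got$n_expressed, 5)
  expect_equal(got$class_table$percent[got$class_table$position_class == "intronic"],
               66.67)
  expect_equal(sum(got$class_table$n), 3)

  clash <- annotated
  clash$transcripts$transcript_id[1] <- "n1"
  expect_error(summarize_catalog(novel, clash), "duplicate")

  empty <- subset_transcripts(novel, character(0))
  got_empty <- summarize_catalog(empty, annotated, classes[0, ])
  expect_equal(got_empty$n_novel, 0)
  expect_equal(nrow(got_empty$class_table), 0)
})
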