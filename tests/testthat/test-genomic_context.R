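test_that("QTL intersection respects half-open boundaries", {
  lnc <- genomic_intervals("chr1", 100, 200, "+")
  lnc$transcript_id <- "lncA"
  qtl_hit <- genomic_intervals("chr1", 150, 300, ".")
  qtl_hit$qtl_id <- "q1"
  qtl_hit$category <- "meat_and_carcass"
  got <- intersect_qtl(lnc, qtl_hit)
  expect_equal(nrow(got$pairs), 1)

  qtl_adj <- genomic_intervals("chr1", 200, 300, ".")
  qtl_adj$qtl_id <- "q2"
  qtl_adj$category <- "health"
  got2 <- intersect_qtl(lnc, qtl_adj)
  expect_equal(nrow(got2$pairs), 0) # [100,200) vs [200,300) do not overlap
})

test_that("QTL intersection equals the quadratic all-pairs oracle", {
  set.seed(31)
  n <- 500
  lnc <- tibble::tibble(
    transcript_id = sprintf("l%03d", 1:n),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample(0:100000, n), strand = "+"
  )
  lnc$end <- lnc$start + sample(100:5000, n, replace = TRUE)
  qtl <- tibble::tibble(
    qtl_id = sprintf("q%03d", 1:n),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample(0:100000, n), strand = ".",
    category = sample(c("meat_and_carcass", "health"), n, replace = TRUE)
  )
  qtl$end <- qtl$start + sample(1000:20000, n, replace = TRUE)
  got <- intersect_qtl(lnc, qtl)
  oracle <- overlap_oracle(lnc, qtl)
  expect_equal(nrow(got$pairs), nrow(oracle))
  got_keys <- sort(paste(got$pairs$transcript_id, got$pairs$qtl_id))
  oracle_keys <- sort(paste(lnc$transcript_id[oracle[, 1]],
                            qtl$qtl_id[oracle[, 2]]))
  expect_equal(got_keys, oracle_keys)
  expect_equal(sum(got$proportions$proportion), 1)
})

test_that("chromosome naming mismatches raise a warning", {
  lnc <- genomic_intervals("chr1", 0, 100)
  lnc$transcript_id <- "l1"
  qtl <- genomic_intervals("1", 0, 100)
  qtl$qtl_id <- "q1"
  qtl$category <- "health"
  expect_warning(intersect_qtl(lnc, qtl), "no shared chromosome")
})

test_that("cis target discovery applies the inclusive 100 kb boundary", {
  gene <- genomic_intervals("chr1", 0, 1000, "+")
  gene$gene_id <- "G1"
  at_gap <- function(gap) {
    lnc <- genomic_intervals("chr1", 1000 + gap, 1000 + gap + 500, "+")
    lnc$transcript_id <- "L1"
    find_cis_ptg(lnc, gene, expressed_gene_ids = "G1", window = 100000)
  }
  exactly <- at_gap(100000)
  expect_equal(nrow(exactly), 1)
  expect_equal(exactly$distance_bp, 100000)
  expect_equal(nrow(at_gap(100001)), 0)

  over <- genomic_intervals("chr1", 500, 1500, "+")
  over$transcript_id <- "L2"
  got_over <- find_cis_ptg(over, gene, "G1")
  expect_equal(got_over$distance_bp, 0)

  # unexpressed genes are not cis targets
  expect_equal(nrow(find_cis_ptg(over, gene, character(0))), 0)
})

test_that("cis discovery equals a quadratic gap oracle on random loci", {
  set.seed(37)
  n <- 120
  lnc <- tibble::tibble(
    transcript_id = sprintf("l%03d", 1:n),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample(0:2000000, n), strand = "+"
  )
  lnc$end <- lnc$start + sample(200:3000, n, replace = TRUE)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample(0:2000000, n), strand = "+"
  )
  genes$end <- genes$start + sample(1000:20000, n, replace = TRUE)
  got <- find_cis_ptg(lnc, genes, genes$gene_id, window = 100000)
  expected <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (lnc$chrom[i] != genes$chrom[j]) next
      gap <- gap_oracle(lnc$start[i], lnc$end[i], genes$start[j], genes$end[j])
      if (gap <= 100000) {
        expected[[length(expected) + 1]] <-
          tibble::tibble(lncrna_id = lnc$transcript_id[i],
                         gene_id = genes$gene_id[j], distance_bp = gap)
      }
    }
  }
  expected <- dplyr::arrange(dplyr::bind_rows(expected), lncrna_id, gene_id)
  got <- dplyr::arrange(got, lncrna_id, gene_id)
  expect_equal(got, expected)
})

test_that("cis direction table cross-tabulates DE flags with concordance", {
  pairs <- tibble::tibble(lncrna_id = c("l1", "l2", "l3"),
                          gene_id = c("g1", "g2", "g3"),
                          distance_bp = c(0, 100, 200))
  lnc_de <- tibble::tibble(transcript_id = c("l1", "l2", "l3"),
                           de_flag = c("up", "up", "down"))
  gene_de <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                            de_flag = c("up", "down", "down"))
  got <- cis_direction_table(pairs, lnc_de, gene_de)
  expect_equal(sum(got$n), 3)
  expect_equal(got$n[got$lnc_flag == "up" & got$gene_flag == "up"], 1)
  expect_true(got$concordant[got$lnc_flag == "down" & got$gene_flag == "down"])
  expect_false(any(got$concordant[got$lnc_flag != got$gene_flag]))
})

test_that("locus spans cover all exons of a transcript or gene", {
  tset <- toy_tset()
  sp <- locus_spans(tset)
  expect_equal(sp$start[sp$transcript_id == "txA"], 0)
  expect_equal(sp$end[sp$transcript_id == "txA"], 400)
  by_gene <- locus_spans(tset, by = "gene_id")
  expect_setequal(by_gene$gene_id, c("gA", "gB"))
})
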