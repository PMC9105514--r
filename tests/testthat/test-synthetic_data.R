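test_that("the generator is deterministic under a fixed seed", {
  spec <- small_quadrant_spec(seed = 11)
  a1 <- generate_annotation(spec)
  a2 <- generate_annotation(spec)
  expect_identical(a1$assembled, a2$assembled)
  expect_identical(a1$truth, a2$truth)
  c1 <- generate_counts(spec, a1)
  c2 <- generate_counts(spec, a2)
  expect_identical(c1$counts_input, c2$counts_input)
  expect_identical(c1$counts_ip, c2$counts_ip)
  expect_identical(c1$windows, c2$windows)
  x1 <- generate_context(spec, a1, c1)
  x2 <- generate_context(spec, a2, c2)
  expect_identical(x1$qtl, x1$qtl)
  expect_identical(x1$ppi_edges, x2$ppi_edges)

  # and a GTF written from the same annotation is byte-identical
  p1 <- withr::local_tempfile(fileext = ".gtf")
  p2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(a1$assembled, p1)
  write_gtf(a2$assembled, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("planted cascade violations produce the planned attrition", {
  study <- small_study()
  truth <- study$annotation$truth$candidates
  res <- suppressMessages(filter_cascade(
    study$annotation$assembled, study$context$coding_potential,
    study$counts$fpkm_input[
      intersect(rownames(study$counts$fpkm_input),
                study$annotation$assembled$transcripts$transcript_id), ,
      drop = FALSE]))
  planted <- table(truth$violation)
  rep <- res$report
  expect_equal(rep$n_removed[rep$stage == "class_code"],
               unname(planted[["class_code"]]))
  expect_equal(rep$n_removed[rep$stage == "length"], unname(planted[["length"]]))
  expect_equal(rep$n_removed[rep$stage == "coding_potential"],
               unname(planted[["coding_potential"]]))
  expect_equal(rep$n_removed[rep$stage == "db_hit"], unname(planted[["db_hit"]]))
  expect_equal(rep$n_removed[rep$stage == "fpkm"], unname(planted[["low_fpkm"]]))
  # survivors are exactly the pass-all candidates
  expect_setequal(res$novel$transcripts$transcript_id,
                  truth$transcript_id[truth$violation == "none"])
})

test_that("FPKM tables are invariant to a common scaling of counts and libraries", {
  study <- small_study()
  cts <- study$counts$counts_input
  f1 <- compute_fpkm(cts, study$counts$lengths)
  f2 <- compute_fpkm(cts * 10, study$counts$lengths,
                     library_sizes = colSums(cts) * 10)
  expect_equal(f1, f2)
})

test_that("a null copula gives near-zero realized correlation", {
  spec <- simulation_spec(n_lncrna = 2000, true_m6a_expression_correlation = 0,
                          quadrant_counts = c(0, 0, 0, 0), n_de_only = 0,
                          seed = 5)
  ann <- generate_annotation(spec)
  cts <- generate_counts(spec, ann, emit_windows = FALSE)
  sm <- cts$samples
  ids <- cts$truth$transcript_id
  mf <- lapply(spec$tissues, function(tt) {
    mfpkm(cts$fpkm_ip[ids, sm$library_id[sm$assay == "IP" & sm$tissue == tt]],
          cts$fpkm_input[ids, sm$library_id[sm$assay == "Input" & sm$tissue == tt]])
  })
  m6a_fc <- log2(mf[[1]]$mfpkm / mf[[2]]$mfpkm)
  inc <- sm$library_id[sm$assay == "Input" & sm$tissue == spec$tissues[1]]
  ine <- sm$library_id[sm$assay == "Input" & sm$tissue == spec$tissues[2]]
  expr_fc <- log2((rowMeans(cts$fpkm_input[ids, inc]) + 1) /
                    (rowMeans(cts$fpkm_input[ids, ine]) + 1))
  both <- cts$truth$modified_sol & cts$truth$modified_edl
  cc <- m6a_expression_correlation(m6a_fc[both], expr_fc[both])
  expect_lt(abs(cc$r), 0.05)
})

test_that("planted truth tables are consistent with the emitted study", {
  study <- small_study()
  truth <- study$counts$truth
  expr <- study$annotation$truth$expression
  # quadrant members drawn from the both-tissue modified set
  members <- truth$transcript_id[truth$quadrant %in%
                                   c("Hyper-Up", "Hypo-Up", "Hyper-Down", "Hypo-Down")]
  expect_true(all(truth$homeostasis_set[match(members, truth$transcript_id)] == "H"))
  # peak truth only covers modified transcripts
  pk <- study$annotation$truth$peaks
  mod <- expr$transcript_id[expr$modified_sol | expr$modified_edl]
  expect_true(all(pk$transcript_id %in% mod))
  # low-FPKM violators have all-zero counts
  zero_ids <- study$annotation$truth$candidates$transcript_id[
    study$annotation$truth$candidates$violation == "low_fpkm"]
  expect_true(all(study$counts$counts_input[zero_ids, ] == 0))
})

test_that("known-site fraction zero labels every peak unknown", {
  spec0 <- simulation_spec(n_coding_genes = 40, n_lncrna = 150, n_qtl = 20,
                           known_site_fraction = 0,
                           quadrant_counts = c(0, 0, 0, 0), n_de_only = 0,
                           seed = 3)
  ann <- generate_annotation(spec0)
  ctx <- generate_context(spec0, ann)
  expect_equal(nrow(ctx$known_sites), 0)
  pk <- ann$truth$peaks
  lnc <- subset_transcripts(
    ann$assembled,
    intersect(pk$transcript_id, ann$assembled$transcripts$transcript_id))
  labeled <- suppressWarnings(assign_and_label(
    tibble::tibble(chrom = pk$chrom, start = pk$summit_genomic - 25,
                   end = pk$summit_genomic + 25, summit = pk$summit_genomic),
    lnc, ctx$known_sites))
  expect_true(all(labeled$novelty == "unknown"))
})

test_that("degenerate QTL category weights concentrate every interval", {
  spec1 <- simulation_spec(n_coding_genes = 40, n_lncrna = 150, n_qtl = 50,
                           qtl_category_weights = c(meat_and_carcass = 1),
                           quadrant_counts = c(0, 0, 0, 0), n_de_only = 0,
                           seed = 3)
  ann <- generate_annotation(spec1)
  ctx <- generate_context(spec1, ann)
  expect_true(all(ctx$qtl$category == "meat_and_carcass"))
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(simulation_spec(true_m6a_expression_correlation = 1), "strictly inside")
  expect_error(simulation_spec(quadrant_counts = c(-1, 0, 0, 0)), "non-negative")
  expect_error(simulation_spec(n_lncrna = 100, quadrant_counts = c(43, 109, 16, 137)),
               "exceed")
  expect_error(generate_annotation(
    simulation_spec(n_coding_genes = 50, n_lncrna = 100,
                    quadrant_counts = c(0, 0, 0, 0), n_de_only = 0),
    chrom_length = 1000),
    "chromosome too short")
})
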