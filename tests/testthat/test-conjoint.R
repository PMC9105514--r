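# Two-sided Fisher exact oracle by enumeration of the hypergeometric support.
fisher_two_sided_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  dens <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

test_that("differential methylation matches the closed-form oracle", {
  got <- differential_methylation(
    ip_a = c(80, 50, 0), input_a = c(20, 50, 0),
    ip_b = c(20, 25, 0), input_b = c(80, 25, 0),
    transcript_id = c("planted", "flat", "empty"))
  expect_equal(got$meth_log2fc[1], 4) # log2((80/20)/(20/80))
  expect_equal(got$pvalue[1], fisher_two_sided_oracle(80, 20, 20, 80),
               tolerance = 1e-10)
  expect_equal(got$meth_log2fc[2], 0)
  expect_equal(got$dm_flag[2], "ns")
  expect_true(is.na(got$meth_log2fc[3]))
  expect_true(is.na(got$pvalue[3]))
})

test_that("a planted 4-fold methylation shift is detected with high sensitivity", {
  set.seed(23)
  n_pos <- 200
  n_null <- 800
  mu <- 200
  draw <- function(mu_vec) rnbinom(length(mu_vec), mu = mu_vec, size = 10)
  ip_a <- draw(c(rep(4 * mu, n_pos), rep(mu, n_null)))
  input_a <- draw(rep(mu, n_pos + n_null))
  ip_b <- draw(rep(mu, n_pos + n_null))
  input_b <- draw(rep(mu, n_pos + n_null))
  got <- differential_methylation(ip_a, input_a, ip_b, input_b,
                                  transcript_id = sprintf("t%04d", 1:(n_pos + n_null)))
  sens <- mean(got$dm_flag[1:n_pos] == "hyper")
  expect_gte(sens, 0.9)
})

make_tables <- function(quadrants) {
  # quadrants: named counts for the four classes plus ns rows
  n <- sum(quadrants)
  ids <- sprintf("lnc%04d", seq_len(n + 50))
  lab <- c(rep(names(quadrants), quadrants), rep("none", 50))
  up <- grepl("Up$", lab)
  down <- grepl("Down$", lab)
  hyper <- grepl("^Hyper", lab)
  de <- tibble::tibble(
    transcript_id = ids,
    log2fc = ifelse(up, 2, ifelse(down, -2, 0.1)),
    pvalue = ifelse(up | down, 1e-6, 0.9),
    padj = ifelse(up | down, 1e-5, 0.95),
    de_flag = ifelse(up, "up", ifelse(down, "down", "ns"))
  )
  dm <- tibble::tibble(
    transcript_id = ids,
    meth_log2fc = ifelse(lab == "none", 0.05, ifelse(hyper, 1.5, -1.5)),
    pvalue = ifelse(lab == "none", 0.8, 1e-6),
    padj = ifelse(lab == "none", 0.9, 1e-5),
    dm_flag = ifelse(lab == "none", "ns", ifelse(hyper, "hyper", "hypo"))
  )
  list(de = de, dm = dm)
}

test_that("four-quadrant classification recovers a constructed sign pattern", {
  tb <- make_tables(c(`Hyper-Up` = 7, `Hypo-Up` = 12, `Hyper-Down` = 3,
                      `Hypo-Down` = 9))
  got <- four_quadrant(tb$de, tb$dm)
  expect_equal(unname(got$counts[c("Hyper-Up", "Hypo-Up", "Hyper-Down", "Hypo-Down")]),
               c(7, 12, 3, 9))
  expect_equal(unname(got$counts["total"]), 31)
  expect_equal(length(got$dme_ids), 31)
  # up-quadrants sum to the significant-up dme ids
  up_ids <- tb$de$transcript_id[tb$de$de_flag == "up"]
  expect_equal(sum(got$counts[c("Hyper-Up", "Hypo-Up")]),
               sum(got$dme_ids %in% up_ids))
})

test_that("four-quadrant output is invariant to row order and handles edge cases", {
  tb <- make_tables(c(`Hyper-Up` = 5, `Hypo-Up` = 0, `Hyper-Down` = 0,
                      `Hypo-Down` = 0))
  got <- four_quadrant(tb$de, tb$dm)
  expect_equal(unname(got$counts[c("Hypo-Up", "Hyper-Down", "Hypo-Down")]),
               c(0, 0, 0))
  shuffled <- four_quadrant(tb$de[sample(nrow(tb$de)), ],
                            tb$dm[sample(nrow(tb$dm)), ])
  expect_equal(shuffled$counts, got$counts)
  expect_setequal(shuffled$dme_ids, got$dme_ids)

  none <- make_tables(c(`Hyper-Up` = 0, `Hypo-Up` = 0, `Hyper-Down` = 0,
                        `Hypo-Down` = 0))
  expect_equal(unname(four_quadrant(none$de, none$dm)$counts["total"]), 0)
})

test_that("swapping tissue labels exchanges Hyper-Up with Hypo-Down", {
  tb <- make_tables(c(`Hyper-Up` = 6, `Hypo-Up` = 4, `Hyper-Down` = 2,
                      `Hypo-Down` = 8))
  fwd <- four_quadrant(tb$de, tb$dm)
  de_swap <- dplyr::mutate(tb$de, log2fc = -log2fc,
                           de_flag = dplyr::recode(de_flag, up = "down",
                                                   down = "up", ns = "ns"))
  dm_swap <- dplyr::mutate(tb$dm, meth_log2fc = -meth_log2fc)
  rev <- four_quadrant(de_swap, dm_swap)
  expect_equal(unname(rev$counts["Hypo-Down"]), unname(fwd$counts["Hyper-Up"]))
  expect_equal(unname(rev$counts["Hyper-Down"]), unname(fwd$counts["Hypo-Up"]))
  expect_equal(unname(rev$counts["Hypo-Up"]), unname(fwd$counts["Hyper-Down"]))
  expect_equal(unname(rev$counts["Hyper-Up"]), unname(fwd$counts["Hypo-Down"]))
})
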