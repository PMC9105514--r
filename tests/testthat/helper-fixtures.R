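# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# A small quadrant-mode study exercising every stage quickly.
small_quadrant_spec <- function(seed = 7) {
  simulation_spec(
    n_coding_genes = 60, n_lncrna = 300, n_qtl = 80,
    quadrant_counts = c(hyper_up = 5, hypo_up = 10, hyper_down = 3, hypo_down = 12),
    n_de_only = 5, seed = seed
  )
}

small_study <- function() {
  cached("small_study", function() {
    suppressMessages(simulate_study(small_quadrant_spec()))
  })
}

# A tiny hand-built transcript set: one 2-exon plus-strand transcript and one
# 2-exon minus-strand transcript.
toy_tset <- function() {
  transcript_set(
    tibble::tibble(
      transcript_id = c("txA", "txB"),
      gene_id = c("gA", "gB"),
      chrom = "chr1", strand = c("+", "-"),
      class_code = c("u", "u"), biotype = "candidate",
      n_exons = c(2L, 2L), length = c(200, 250)
    ),
    tibble::tibble(
      transcript_id = c("txA", "txA", "txB", "txB"),
      chrom = "chr1",
      start = c(0, 300, 1000, 1500),
      end = c(100, 400, 1150, 1600),
      strand = c("+", "+", "-", "-"),
      exon_rank = c(1L, 2L, 1L, 2L)
    )
  )
}

# Brute-force longest-ORF oracle: enumerate every in-frame ATG..stop pair.
orf_oracle <- function(seq) {
  s <- toupper(gsub("U", "T", seq, fixed = TRUE))
  n <- nchar(s)
  best <- 0L
  for (i in seq_len(max(0, n - 2))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      codon <- substr(s, j, j + 2)
      if (codon %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 2 - i + 1)
        break
      }
      j <- j + 3
    }
  }
  best
}

# Quadratic interval-overlap oracle (0-based half-open).
overlap_oracle <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out)
}

# Boundary-gap between two 0-based half-open intervals (0 if overlapping).
gap_oracle <- function(s1, e1, s2, e2) {
  if (s1 < e2 && s2 < e1) return(0)
  if (s2 >= e1) return(s2 - e1)
  s1 - e2
}

# All permutations of seq_len(n) as a matrix (n! rows).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (k in seq_len(n)) {
    block <- cbind(rep(k, nrow(sub)), ifelse(sub >= k, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Mann-Kendall S statistic of a sequence.
mk_s <- function(x) {
  sgn <- sign(outer(x, x, "-"))
  sum(sgn[lower.tri(sgn)])
}

dinuc_counts <- function(s) {
  chars <- strsplit(s, "")[[1]]
  table(paste0(chars[-length(chars)], chars[-1]))
}
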