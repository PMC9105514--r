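#' Construct a table of genomic intervals
#'
#' Intervals use the 0-based half-open convention throughout the package:
#' `start` is the 0-based position of the first base, `end` is one past the
#' last base. GTF input (1-based, closed) is converted at the boundary.
#'
#' @param chrom Character vector of chromosome names (non-empty).
#' @param start,end Integer vectors; `0 <= start < end` is enforced.
#' @param strand Strand of each interval: `"+"`, `"-"` or `"."` (unstranded).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("chrom must be non-empty")
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad) > 0) {
    stop("invalid interval(s) at record index ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  }
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be one of '+', '-', '.'")
  tibble::tibble(chrom = as.character(chrom), start = start, end = end,
                 strand = rep_len(strand, length(chrom)))
}

#' Convert an interval table to a GRanges object
#'
#' @param df A tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `strand`; extra columns become metadata columns.
#' @return A [GenomicRanges::GRanges] (1-based closed, `"."` mapped to `"*"`).
#' @export
intervals_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) ifelse(df$strand == ".", "*", df$strand) else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra) > 0) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[extra])
  }
  gr
}

#' Convert a GRanges object to a 0-based half-open interval table
#'
#' @param gr A [GenomicRanges::GRanges].
#' @return A tibble with `chrom`, `start`, `end`, `strand` plus metadata columns.
#' @export
granges_to_intervals <- function(gr) {
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = as.numeric(BiocGenerics::end(gr)),
    strand = strand
  )
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc) > 0) out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(mc)))
  out
}

#' Bundle transcript models into a transcript set
#'
#' A transcript set is the package's container for exon-structured transcript
#' models: a `transcripts` tibble (one row per transcript) and an `exons`
#' tibble (one row per exon, 0-based half-open coordinates, sorted).
#'
#' @param transcripts Tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `class_code`, `biotype`, `n_exons`, `length`.
#' @param exons Tibble with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`, `exon_rank`.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(transcripts, exons) {
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand") %in% names(transcripts)),
            all(c("transcript_id", "start", "end") %in% names(exons)))
  structure(list(transcripts = tibble::as_tibble(transcripts),
                 exons = tibble::as_tibble(exons)),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons\n")
  bt <- table(x$transcripts$biotype)
  if (length(bt) > 0) {
    cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a transcript set by transcript id
#'
#' @param tset A `transcript_set`.
#' @param ids Transcript ids to keep.
#' @return A `transcript_set` restricted to `ids`.
#' @export
subset_transcripts <- function(tset, ids) {
  transcript_set(
    dplyr::filter(tset$transcripts, .data$transcript_id %in% ids),
    dplyr::filter(tset$exons, .data$transcript_id %in% ids)
  )
}

# Check raw GTF/BED lines for a minimum field count; error names the line.
check_field_count <- function(lines, min_fields, what) {
  data_idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(data_idx) == 0) return(integer(0))
  nf <- lengths(strsplit(lines[data_idx], "\t", fixed = TRUE))
  bad <- data_idx[nf < min_fields]
  if (length(bad) > 0) {
    stop("malformed ", what, " line ", bad[1], ": expected at least ",
         min_fields, " tab-separated fields")
  }
  data_idx
}

#' Read transcript models from a GTF file
#'
#' Exon features are grouped per transcript and sorted by coordinate; GTF
#' 1-based closed coordinates are converted to the internal 0-based half-open
#' convention. Overlapping exons within one transcript are merged with a
#' warning.
#'
#' @param path Path to a GTF file (Ensembl dialect) with `exon` features
#'   carrying `transcript_id` and `gene_id` attributes. Optional attributes
#'   `class_code` and `transcript_biotype` are preserved.
#' @return A [transcript_set].
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  check_field_count(lines, 9L, "GTF")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) {
    return(transcript_set(
      tibble::tibble(transcript_id = character(), gene_id = character(),
                     chrom = character(), strand = character(),
                     class_code = character(), biotype = character(),
                     n_exons = integer(), length = numeric()),
      tibble::tibble(transcript_id = character(), chrom = character(),
                     start = numeric(), end = numeric(), strand = character(),
                     exon_rank = integer())
    ))
  }
  ex <- tibble::tibble(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = as.numeric(BiocGenerics::end(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    class_code = if (!is.null(gr$class_code)) gr$class_code else NA_character_,
    biotype = if (!is.null(gr$transcript_biotype)) gr$transcript_biotype else NA_character_
  )
  ex <- dplyr::arrange(ex, .data$transcript_id, .data$start)
  # merge overlapping exons within a transcript
  ex <- dplyr::group_by(ex, .data$transcript_id)
  ex <- dplyr::mutate(ex, new_block = cumsum(
    c(TRUE, .data$start[-1] >= cummax(.data$end)[-dplyr::n()])
  ))
  n_before <- nrow(ex)
  ex <- dplyr::summarise(
    dplyr::group_by(ex, .data$transcript_id, .data$new_block),
    gene_id = .data$gene_id[1], chrom = .data$chrom[1],
    start = min(.data$start), end = max(.data$end),
    strand = .data$strand[1], class_code = .data$class_code[1],
    biotype = .data$biotype[1], .groups = "drop"
  )
  if (nrow(ex) < n_before) {
    warning("merged ", n_before - nrow(ex), " overlapping exon(s) within transcripts")
  }
  ex <- dplyr::arrange(ex, .data$transcript_id, .data$start)
  ex <- dplyr::mutate(dplyr::group_by(ex, .data$transcript_id),
                      exon_rank = dplyr::row_number())
  ex <- dplyr::ungroup(ex)
  tx <- dplyr::summarise(
    dplyr::group_by(ex, .data$transcript_id),
    gene_id = .data$gene_id[1], chrom = .data$chrom[1], strand = .data$strand[1],
    class_code = .data$class_code[1], biotype = .data$biotype[1],
    n_exons = dplyr::n(), length = sum(.data$end - .data$start),
    .groups = "drop"
  )
  transcript_set(tx, dplyr::select(ex, "transcript_id", "chrom", "start",
                                   "end", "strand", "exon_rank"))
}

#' Write a transcript set to a GTF file
#'
#' @param tset A [transcript_set].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tset, path, source = "lncm6a") {
  ex <- dplyr::left_join(
    tset$exons,
    dplyr::select(tset$transcripts, "transcript_id", "gene_id",
                  "class_code", "biotype"),
    by = "transcript_id"
  )
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ifelse(ex$strand == ".", "*", ex$strand)
  )
  gr$source <- source
  gr$type <- "exon"
  gr$transcript_id <- ex$transcript_id
  gr$gene_id <- ex$gene_id
  if (!all(is.na(ex$class_code))) gr$class_code <- ex$class_code
  if (!all(is.na(ex$biotype))) gr$transcript_biotype <- ex$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open, matching the internal convention; coordinates are
#' taken as-is. An empty file yields an empty table. Records with
#' `start >= end` are rejected with their record index.
#'
#' @param path Path to a BED3/BED6(+) file.
#' @param extra_cols Named character vector of types for columns beyond the
#'   standard six, as in `rtracklayer::import.bed(extraCols = ...)`.
#' @return A tibble with `chrom`, `start`, `end`, `strand` plus `name`,
#'   `score` and any extra columns present.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  lines <- readLines(path)
  idx <- check_field_count(lines, 3L, "BED")
  if (length(idx) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), strand = character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  starts <- as.numeric(vapply(fields, `[`, "", 2L))
  ends <- as.numeric(vapply(fields, `[`, "", 3L))
  bad <- which(!(starts < ends))
  if (length(bad) > 0) {
    stop("BED record ", bad[1], " rejected: start >= end")
  }
  gr <- if (is.null(extra_cols)) {
    rtracklayer::import(path, format = "bed")
  } else {
    rtracklayer::import(path, format = "bed", extraCols = extra_cols)
  }
  granges_to_intervals(gr)
}

#' Write genomic intervals to a BED file
#'
#' @param df Interval table (`chrom`, `start`, `end`, optional `strand`,
#'   `name`, `score`, extra columns written as BED6+ fields).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    name, score, strand)
  extra <- setdiff(names(df), c("chrom", "start", "end", "name", "score", "strand"))
  if (length(extra) > 0) out <- cbind(out, df[extra])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV table with header
#'
#' Missing numeric cells propagate as `NA`; unknown columns are preserved.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a TSV table with header
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  readr::write_tsv(df, path)
  invisible(path)
}

#' Build the run configuration
#'
#' Thresholds driving every stage of the pipeline. Defaults follow the study
#' design: novel lncRNAs must be at least 200 nt with FPKM >= 0.5 in at least
#' one sample (2.0 for single-exon transcripts); differential calls use
#' Benjamini-Hochberg adjusted p < 0.05 and |log2 fold change| >= 1 for
#' expression; cis target genes lie within 100 kb; PPI edges require a
#' combined score > 0.4; MCODE uses degree cutoff 2, node score cutoff 0.3,
#' k-core 2 and maximum depth 100.
#'
#' @param ... Named overrides of individual thresholds.
#' @param path Optional YAML file of overrides (flat keys).
#' @return A `run_config` list.
#' @export
run_config <- function(..., path = NULL) {
  cfg <- list(
    min_length_nt = 200,
    fpkm_min = 0.5,
    fpkm_min_single_exon = 2.0,
    de_padj = 0.05,
    de_abs_log2fc = 1.0,
    dm_padj = 0.05,
    peak_padj = 0.05,
    input_fpkm_floor = 0.5,
    cis_window_bp = 100000,
    ppi_score_min = 0.4,
    mcode_degree_cutoff = 2,
    mcode_node_score_cutoff = 0.3,
    mcode_k_core = 2,
    mcode_max_depth = 100,
    peak_window_nt = 100,
    peak_step_nt = 50,
    random_seed = 1
  )
  if (!is.null(path)) {
    onto <- yaml::read_yaml(path)
    for (k in names(onto)) cfg[[k]] <- onto[[k]]
  }
  dots <- list(...)
  for (k in names(dots)) cfg[[k]] <- dots[[k]]
  num <- setdiff(names(cfg), "random_seed")
  vals <- unlist(cfg[num])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thresholds must be finite and positive")
  }
  structure(cfg, class = "run_config")
}

#' Hash of a configuration (or any R object)
#'
#' @param x Object to hash.
#' @return Character scalar hash.
#' @export
config_hash <- function(x) {
  rlang::hash(unclass(x))
}

#' Log a pipeline stage
#'
#' Writes `(records_in, records_out)` and the configuration hash to stderr
#' and, optionally, to a run log file.
#'
#' @param stage Stage name.
#' @param n_in,n_out Record counts entering and leaving the stage.
#' @param config Optional `run_config`; its hash is logged.
#' @param log_file Optional path appended to.
#' @return A one-row tibble with the logged fields, invisibly.
#' @export
log_stage <- function(stage, n_in, n_out, config = NULL, log_file = NULL) {
  h <- if (is.null(config)) NA_character_ else substr(config_hash(config), 1, 8)
  msg <- sprintf("[%s] records_in=%d records_out=%d config=%s",
                 stage, as.integer(n_in), as.integer(n_out),
                 ifelse(is.na(h), "-", h))
  message(msg)
  if (!is.null(log_file)) cat(msg, "\n", file = log_file, append = TRUE, sep = "")
  invisible(tibble::tibble(stage = stage, n_in = as.integer(n_in),
                           n_out = as.integer(n_out), config_hash = h))
}
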