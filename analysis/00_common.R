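# Shared study definitions for the analysis scripts.
#
# Two synthetic scenarios cover the two halves of the analysis:
#  * the ASSOCIATION scenario (copula mode) plants a continuous coupling of
#    0.72 between m6A-level and expression fold changes, for the
#    homeostasis/correlation analyses;
#  * the CONJOINT scenario (quadrant mode) plants 305 dme-lncRNAs with the
#    observed quadrant counts (43 Hyper-Up, 109 Hypo-Up, 16 Hyper-Down,
#    137 Hypo-Down) plus 29 DE-only lncRNAs, for the differential /
#    QTL / network analyses.

suppressMessages(library(lncm6a))

results_dir <- function(sub = NULL) {
  d <- if (is.null(sub)) "results" else file.path("results", sub)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

association_spec <- function(seed = 1) {
  simulation_spec(n_lncrna = 2000, true_m6a_expression_correlation = 0.72,
                  quadrant_counts = c(0, 0, 0, 0), n_de_only = 0, seed = seed)
}

conjoint_spec <- function(seed = 1) {
  simulation_spec(seed = seed) # defaults carry the planted quadrant design
}

# Deterministic regeneration keeps every script self-contained.
conjoint_study <- function(seed = 1) {
  message("simulating the conjoint-scenario study (deterministic, seed ",
          seed, ") ...")
  suppressMessages(simulate_study(conjoint_spec(seed)))
}

association_study <- function(seed = 1) {
  spec <- association_spec(seed)
  message("simulating the association-scenario study (deterministic, seed ",
          seed, ") ...")
  ann <- generate_annotation(spec)
  cts <- suppressMessages(generate_counts(spec, ann, emit_windows = FALSE))
  list(spec = spec, annotation = ann, counts = cts)
}
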