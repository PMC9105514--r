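#' Build a score-filtered PPI graph
#'
#' Retains edges with combined score strictly greater than `score_min`
#' (STRING-style confidence filtering), drops self-loops, and collapses
#' duplicate edges keeping the maximum score. The result is a simple
#' undirected [igraph::igraph] with a `score` edge attribute.
#'
#' @param edges Tibble with columns `protein_a`, `protein_b`,
#'   `combined_score` (scores in `[0, 1]`).
#' @param score_min Strict lower bound on retained combined scores.
#' @return An igraph object.
#' @export
build_ppi_graph <- function(edges, score_min = 0.4) {
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  if (any(edges$combined_score < 0 | edges$combined_score > 1)) {
    stop("combined scores must lie in [0, 1]")
  }
  keep <- edges$combined_score > score_min & edges$protein_a != edges$protein_b
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  # canonical unordered pair, keep max score
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  dedup <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(a = a, b = b, score = edges$combined_score),
                    .data$a, .data$b),
    score = max(.data$score), .groups = "drop")
  g <- igraph::graph_from_data_frame(dedup, directed = FALSE)
  igraph::E(g)$score <- dedup$score
  g
}

# MCODE vertex weight: the highest-k-core number of the closed neighborhood
# times the density of that core (the core-clustering coefficient).
mcode_weights <- function(g, degree_cutoff) {
  vs <- igraph::V(g)$name
  deg <- igraph::degree(g)
  w <- stats::setNames(numeric(length(vs)), vs)
  for (v in vs) {
    if (deg[[v]] < degree_cutoff) next
    nb <- c(v, igraph::neighbors(g, v)$name)
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) next
    core_sub <- igraph::induced_subgraph(sub, names(core)[core >= kmax])
    nv <- igraph::vcount(core_sub)
    dens <- if (nv > 1) {
      2 * igraph::ecount(core_sub) / (nv * (nv - 1))
    } else 0
    w[[v]] <- kmax * dens
  }
  w
}

#' MCODE molecular-complex detection
#'
#' Finds locally dense regions of a PPI graph by node weighting and seeded
#' expansion. Each vertex is weighted by the product of the highest-k-core
#' number of its closed neighborhood and that core's density (vertices with
#' degree below `degree_cutoff` get weight 0). Complexes grow outward from
#' the highest-weight unvisited seed, admitting neighbors whose weight is at
#' least `seed_weight * (1 - node_score_cutoff)` up to `max_depth`;
#' singly-connected members are trimmed (haircut) and complexes lacking a
#' k-core of order `k_core` are discarded. Complexes are vertex-disjoint
#' (no fluff) and scored by density x size; ties break by lexicographic id.
#'
#' @param g An undirected simple [igraph::igraph] with named vertices.
#' @param degree_cutoff Minimum degree for a nonzero weight.
#' @param node_score_cutoff Admission slack relative to the seed weight.
#' @param k_core Minimum core order a complex must contain.
#' @param max_depth Maximum expansion depth from the seed.
#' @return A tibble of clusters: `rank`, `score`, `n_nodes`, `seed`,
#'   `members` (list column, sorted ids).
#' @export
mcode <- function(g, degree_cutoff = 2, node_score_cutoff = 0.3,
                  k_core = 2, max_depth = 100) {
  empty <- tibble::tibble(rank = integer(), score = numeric(),
                          n_nodes = integer(), seed = character(),
                          members = list())
  if (igraph::vcount(g) == 0) return(empty)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  w <- mcode_weights(g, degree_cutoff)
  order_ids <- names(sort(w, decreasing = TRUE))
  # deterministic tie-break by id
  order_ids <- order_ids[order(-w[order_ids], order_ids)]
  visited <- stats::setNames(rep(FALSE, length(w)), names(w))
  clusters <- list()
  for (seed in order_ids) {
    if (visited[[seed]] || w[[seed]] <= 0) next
    threshold <- w[[seed]] * (1 - node_score_cutoff)
    members <- seed
    visited[[seed]] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in sort(igraph::neighbors(g, v)$name)) {
          if (!visited[[u]] && w[[u]] >= threshold) {
            visited[[u]] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    sub <- igraph::induced_subgraph(g, members)
    # haircut: drop singly-connected vertices
    repeat {
      low <- igraph::V(sub)$name[igraph::degree(sub) < 2]
      low <- setdiff(low, character(0))
      if (length(low) == 0 || igraph::vcount(sub) <= 2) break
      keep <- setdiff(igraph::V(sub)$name, low)
      if (length(keep) == length(igraph::V(sub)$name)) break
      visited[low] <- FALSE # trimmed nodes may seed or join later clusters
      sub <- igraph::induced_subgraph(sub, keep)
    }
    nv <- igraph::vcount(sub)
    if (nv < 2 || max(igraph::coreness(sub)) < k_core) {
      next
    }
    dens <- 2 * igraph::ecount(sub) / (nv * (nv - 1))
    clusters[[length(clusters) + 1]] <- list(
      members = sort(igraph::V(sub)$name), seed = seed,
      score = dens * nv, n_nodes = as.integer(nv)
    )
  }
  if (length(clusters) == 0) return(empty)
  scores <- vapply(clusters, `[[`, 0, "score")
  first_member <- vapply(clusters, function(cl) cl$members[1], "")
  ord <- order(-scores, first_member)
  tibble::tibble(
    rank = seq_along(ord),
    score = scores[ord],
    n_nodes = vapply(clusters, `[[`, 0L, "n_nodes")[ord],
    seed = vapply(clusters, `[[`, "", "seed")[ord],
    members = lapply(clusters[ord], `[[`, "members")
  )
}

#' Hypergeometric term enrichment
#'
#' One-sided hypergeometric upper-tail test of each term's overlap with a
#' query gene set against a universe, BH-adjusted across terms. Terms with
#' no universe genes are skipped with a warning. Significance follows the
#' raw p < 0.05 convention used for GO/pathway calls; the BH-adjusted
#' p-value is also reported.
#'
#' @param genes Query gene set (must be a subset of `universe`).
#' @param term_table Tibble with `term` and `gene_id` columns.
#' @param universe Background gene universe.
#' @param p_cutoff Significance threshold on the raw p-value.
#' @return Tibble with `term`, `term_size`, `overlap`, `pvalue`, `padj`,
#'   `significant`.
#' @export
term_enrichment <- function(genes, term_table, universe, p_cutoff = 0.05) {
  stray <- setdiff(genes, universe)
  if (length(stray) > 0) {
    stop("query genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  genes <- unique(genes)
  universe <- unique(universe)
  n_uni <- length(universe)
  n_query <- length(genes)
  terms <- split(term_table$gene_id, term_table$term)
  term_in_uni <- lapply(terms, intersect, universe)
  empty <- names(terms)[lengths(term_in_uni) == 0]
  if (length(empty) > 0) {
    warning("term(s) with no universe genes skipped: ",
            paste(utils::head(empty, 5), collapse = ", "))
    term_in_uni <- term_in_uni[lengths(term_in_uni) > 0]
  }
  if (length(term_in_uni) == 0) {
    return(tibble::tibble(term = character(), term_size = integer(),
                          overlap = integer(), pvalue = numeric(),
                          padj = numeric(), significant = logical()))
  }
  term_size <- lengths(term_in_uni)
  overlap <- vapply(term_in_uni, function(tg) length(intersect(tg, genes)), 0L)
  pvalue <- stats::phyper(overlap - 1, term_size, n_uni - term_size, n_query,
                          lower.tail = FALSE)
  out <- tibble::tibble(
    term = names(term_in_uni), term_size = as.integer(term_size),
    overlap = as.integer(overlap), pvalue = as.numeric(pvalue),
    padj = benjamini_hochberg(as.numeric(pvalue))
  )
  out$significant <- out$pvalue < p_cutoff
  dplyr::arrange(out, .data$pvalue, .data$term)
}
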