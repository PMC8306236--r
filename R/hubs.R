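#' Build an undirected simple PPI graph
#'
#' Self-loops and duplicate pairs are dropped.  Target genes without any
#' interaction may be added as isolated vertices through `nodes`; such
#' vertices receive the minimum value of every centrality and therefore
#' rank last.
#'
#' @param edges Data.frame with columns `gene_a`, `gene_b`.
#' @param nodes Optional character vector of vertex names to include
#'   even when isolated.
#' @return An undirected simple igraph object.
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  a <- toupper(trimws(edges$gene_a))
  b <- toupper(trimws(edges$gene_b))
  keep <- a != b
  el <- cbind(a[keep], b[keep])
  vnames <- sort(unique(c(el[, 1], el[, 2], toupper(nodes))))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(vnames, igraph::V(g)$name)),
                            name = setdiff(vnames, igraph::V(g)$name))
  igraph::simplify(g)
}

#' Node centralities for hub selection
#'
#' Computes one of the four node-ranking measures used for hub
#' selection, with the conventions of the cytoHubba tool:
#' * `Clo` (closeness): sum of reciprocal shortest-path distances to all
#'   other nodes; unreachable nodes contribute 0.
#' * `EC` (eccentricity): reciprocal of the maximum shortest-path
#'   distance to any node reachable from `v`.
#' * `Rad` (radiality): sum over the other nodes `w` of `v`'s component
#'   of `(diameter + 1 - dist(v, w))`, divided by the component size
#'   minus one; the diameter is that of the component.
#' * `EPC` (edge-percolated component): Monte-Carlo mean, over seeded
#'   percolation replicates in which every edge is independently kept
#'   with probability `epc_edge_prob`, of the size of the component
#'   containing `v` in the surviving graph.
#'
#' Distance-based measures are computed within connected components;
#' isolated vertices score 0 (EPC: 1, its own component), the minimum.
#'
#' @param ppi An undirected igraph object.
#' @param measure One of `"EPC"`, `"EC"`, `"Clo"`, `"Rad"`.
#' @param seed Integer seed for the EPC Monte-Carlo draw.
#' @param epc_replicates Number of percolation replicates.
#' @param epc_edge_prob Edge retention probability.
#' @return Named numeric vector of centrality values.
#' @export
compute_centrality <- function(ppi, measure = c("EPC", "EC", "Clo", "Rad"),
                               seed = 1L, epc_replicates = 1000,
                               epc_edge_prob = 0.5) {
  if (length(measure) == 1 && !measure %in% c("EPC", "EC", "Clo", "Rad")) {
    stop(sprintf("unknown centrality measure: %s", measure), call. = FALSE)
  }
  measure <- match.arg(measure)
  if (igraph::vcount(ppi) == 0) stop("empty PPI graph", call. = FALSE)
  vn <- igraph::V(ppi)$name
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(ppi)))
  if (measure == "EPC") {
    return(stats::setNames(
      epc_centrality(ppi, seed = seed, replicates = epc_replicates,
                     edge_prob = epc_edge_prob), vn))
  }
  d <- igraph::distances(ppi)
  diag(d) <- Inf  # exclude self-distances from all sums and maxima
  finite <- is.finite(d)
  val <- switch(measure,
    Clo = rowSums(ifelse(finite, 1 / d, 0)),
    EC = {
      ecc <- apply(d, 1, function(r) {
        f <- r[is.finite(r)]
        if (length(f) == 0) Inf else max(f)
      })
      ifelse(is.finite(ecc), 1 / ecc, 0)
    },
    Rad = {
      comp <- igraph::components(ppi)$membership
      out <- numeric(length(comp))
      for (cid in unique(comp)) {
        members <- which(comp == cid)
        if (length(members) < 2) next
        dc <- d[members, members, drop = FALSE]
        delta <- max(dc[is.finite(dc)])
        for (k in seq_along(members)) {
          dv <- dc[k, -k]
          out[members[k]] <- sum(delta + 1 - dv) / (length(members) - 1)
        }
      }
      out
    })
  stats::setNames(as.numeric(val), vn)
}

# Monte-Carlo edge percolation; bit-reproducible for a fixed seed.
epc_centrality <- function(ppi, seed = 1L, replicates = 1000,
                           edge_prob = 0.5) {
  n <- igraph::vcount(ppi)
  m <- igraph::ecount(ppi)
  acc <- numeric(n)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(replicates)) {
    keep <- stats::runif(m) < edge_prob
    sub <- igraph::delete_edges(ppi, which(!keep))
    comp <- igraph::components(sub)
    acc <- acc + comp$csize[comp$membership]
  }
  acc / replicates
}

#' Dense ranking of scores
#'
#' Rank 1 is the best score.  Tied scores share one rank and the next
#' distinct score's rank increases by exactly one, regardless of the
#' size of the tied group.
#'
#' @param values Named numeric vector.
#' @param higher_is_better If `TRUE` (default) the largest value ranks
#'   first.
#' @return Named integer vector of dense ranks.
#' @export
dense_rank <- function(values, higher_is_better = TRUE) {
  stopifnot(all(is.finite(values)))
  u <- sort(unique(values), decreasing = higher_is_better)
  stats::setNames(match(values, u), names(values))
}

#' Centrality and rank table of a PPI network
#'
#' Computes all four centralities, their dense ranks and each measure's
#' median rank.
#'
#' @param ppi An undirected igraph object.
#' @inheritParams compute_centrality
#' @return Data.frame with one row per node: value and dense-rank
#'   columns per measure (`EPC`, `EC`, `Clo`, `Rad`, `rank_EPC`, ...);
#'   the median rank of each measure is attached as attribute
#'   `median_ranks`.
#' @export
centrality_rank_table <- function(ppi, seed = 1L, epc_replicates = 1000,
                                  epc_edge_prob = 0.5) {
  measures <- c("EPC", "EC", "Clo", "Rad")
  vals <- lapply(measures, function(m) {
    compute_centrality(ppi, m, seed = seed,
                       epc_replicates = epc_replicates,
                       epc_edge_prob = epc_edge_prob)
  })
  names(vals) <- measures
  out <- data.frame(node = names(vals$EPC), stringsAsFactors = FALSE)
  med <- numeric(length(measures))
  names(med) <- measures
  for (m in measures) {
    out[[m]] <- unname(vals[[m]])
    r <- dense_rank(vals[[m]], higher_is_better = TRUE)
    out[[paste0("rank_", m)]] <- unname(r)
    med[m] <- stats::median(r)
  }
  attr(out, "median_ranks") <- med
  out
}

#' Median-rank aggregate hub score
#'
#' Starting from 0, a node's score gains one point for each of the four
#' measures in which its dense rank is strictly less than the median
#' rank of all nodes in that measure.  Scores therefore lie in 0..4.
#'
#' @param rank_table Output of [centrality_rank_table()] (or any
#'   data.frame with columns `node` and `rank_EPC`, `rank_EC`,
#'   `rank_Clo`, `rank_Rad`).
#' @return Data.frame with columns `node` and `score`.
#' @export
aggregate_score <- function(rank_table) {
  measures <- c("EPC", "EC", "Clo", "Rad")
  cols <- paste0("rank_", measures)
  missing <- setdiff(cols, names(rank_table))
  if (length(missing) > 0) {
    stop(sprintf("missing rank column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  med <- attr(rank_table, "median_ranks")
  if (is.null(med)) {
    med <- vapply(cols, function(cn) stats::median(rank_table[[cn]]),
                  numeric(1))
    names(med) <- measures
  }
  s <- rowSums(vapply(measures, function(m) {
    rank_table[[paste0("rank_", m)]] < med[m]
  }, logical(nrow(rank_table))))
  data.frame(node = rank_table$node, score = as.integer(s),
             stringsAsFactors = FALSE)
}

#' Select hub genes
#'
#' A target is a hub when its aggregate score exceeds 1 and more than
#' one compound interacts with it in the global compound-target
#' network.  Curated genes in `manual_includes` are added regardless
#' and flagged.
#'
#' @param scores Data.frame with columns `node`, `score` (see
#'   [aggregate_score()]).
#' @param compound_counts Named integer vector: target gene -> number of
#'   interacting compounds in the global bipartite network.
#' @param manual_includes Character vector of gene symbols to force in.
#' @return Data.frame with columns `node`, `score`, `n_compounds`,
#'   `hub`, `manual` for every scored or manually included gene.
#' @export
select_hubs <- function(scores, compound_counts,
                        manual_includes = character()) {
  manual_includes <- toupper(manual_includes)
  nodes <- union(scores$node, manual_includes)
  absent <- setdiff(manual_includes, scores$node)
  if (length(absent) > 0) {
    warning(sprintf("manual include(s) absent from scored network: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  s <- scores$score[match(nodes, scores$node)]
  cnt <- unname(compound_counts[nodes])
  cnt[is.na(cnt)] <- 0L
  manual <- nodes %in% manual_includes
  hub <- (!is.na(s) & s > 1 & cnt > 1) | manual
  out <- data.frame(node = nodes, score = s,
                    n_compounds = as.integer(unname(cnt)),
                    hub = hub, manual = manual, stringsAsFactors = FALSE)
  out <- out[order(-out$hub, -ifelse(is.na(out$score), -1, out$score),
                   out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compounds per target in a compound-target table
#'
#' @param cti_table Data.frame with columns `compound_id`,
#'   `target_gene` and optionally `origin`.
#' @param origin Optional filter: count only edges of this origin
#'   (`"known"` or `"predicted"`); default counts both.
#' @return Named integer vector target gene -> distinct compound count.
#' @export
compound_counts_per_target <- function(cti_table, origin = NULL) {
  x <- cti_table
  if (!is.null(origin)) x <- x[x$origin == origin, , drop = FALSE]
  x <- unique(x[, c("compound_id", "target_gene")])
  tab <- table(x$target_gene)
  stats::setNames(as.integer(tab), names(tab))
}
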