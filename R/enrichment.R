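#' Hypergeometric pathway over-representation
#'
#' For each annotated gene set, tests whether the hub genes contain more
#' members of the set than expected under uniform sampling from the
#' background, with the exact hypergeometric upper tail
#' `P(X >= k)` for `k` hub genes among `K` pathway genes, `n` hub genes
#' and `N` background genes.  Pathway memberships are intersected with
#' the background first.
#'
#' @param hub_genes Character vector of gene symbols (must lie in the
#'   background).
#' @param annotation Named list of gene sets (see [read_gmt()]).
#' @param background Character vector of background symbols; default is
#'   the union of all annotated genes.
#' @param fdr_threshold Benjamini-Hochberg significance cutoff used for
#'   the `significant` flag.
#' @return Data.frame with one row per pathway: `pathway`, `k`, `K`,
#'   `n`, `N`, `overlap` (comma-separated symbols), `p_value`, `fdr`,
#'   `significant`, `retained` (initialized to `significant`; see
#'   [curate_pathways()]), sorted by p-value.
#' @export
hypergeom_enrich <- function(hub_genes, annotation, background = NULL,
                             fdr_threshold = 0.05) {
  if (is.null(background)) {
    background <- unique(unlist(annotation, use.names = FALSE))
  }
  background <- normalize_gene_symbols(background)
  if (length(background) == 0) stop("empty background", call. = FALSE)
  hub_genes <- normalize_gene_symbols(hub_genes)
  outside <- setdiff(hub_genes, background)
  if (length(outside) > 0) {
    warning(sprintf("%d hub gene(s) outside background dropped: %s",
                    length(outside),
                    paste(utils::head(outside, 5), collapse = ", ")),
            call. = FALSE)
    hub_genes <- intersect(hub_genes, background)
  }
  N <- length(background)
  n <- length(hub_genes)
  rows <- lapply(seq_along(annotation), function(i) {
    set_genes <- intersect(normalize_gene_symbols(annotation[[i]]),
                           background)
    K <- length(set_genes)
    hits <- intersect(hub_genes, set_genes)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = names(annotation)[i], k = k, K = K, n = n, N = N,
               overlap = paste(sort(hits), collapse = ","),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < fdr_threshold
  out$retained <- out$significant
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone in p-value
#' rank, capped at 1).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of adjusted values.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Curate enriched pathways by exclusion patterns
#'
#' Drops significant pathways whose names match any exclusion pattern
#' (literal substring or glob, case-insensitive), emulating the
#' literature-based removal of pathways unrelated to the disease (e.g.
#' cancer pathways).  An explicit keep list overrides the patterns.
#' p-values and FDR values are never altered; only the `retained` flag
#' changes.
#'
#' @param results Enrichment data.frame (see [hypergeom_enrich()]).
#' @param exclude_patterns Character vector of glob patterns (e.g.
#'   `"*cancer*"`).
#' @param keep_list Optional character vector of pathway names never
#'   removed.
#' @return The input with an updated `retained` column; removals are
#'   recorded in attribute `removals` (named vector pathway -> pattern).
#' @export
curate_pathways <- function(results, exclude_patterns = character(),
                            keep_list = character()) {
  retained <- results$significant
  removals <- character(0)
  for (pat in exclude_patterns) {
    rx <- utils::glob2rx(pat)
    hit <- grepl(rx, results$pathway, ignore.case = TRUE) &
      !(results$pathway %in% keep_list)
    newly <- hit & retained
    if (any(newly)) {
      removals <- c(removals,
                    stats::setNames(rep(pat, sum(newly)),
                                    results$pathway[newly]))
    }
    retained <- retained & !hit
  }
  results$retained <- retained
  attr(results, "removals") <- removals
  results
}
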