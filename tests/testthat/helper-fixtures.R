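# Fixture builders shared across the suite.  All fixtures are built in
# code; the critical-interaction worked example uses the values printed
# in the study (docking scores of the seven predicted interactions, the
# three known critical interactions, and the reported maximum fold
# changes of MOL43, MOL10 and MOL17).

fc_cols <- sprintf("fc_%02d", 1:16)

# A compound table row with a flat series at `base` and a single spiked
# period carrying `fc_max` (when fc_max > base).
make_compounds <- function(ids,
                           compound_class = "prototype",
                           herb_origin = "RA",
                           fc_max = 20,
                           base = 1,
                           structure = "CCO",
                           class_tags = "") {
  n <- length(ids)
  compound_class <- rep_len(compound_class, n)
  herb_origin <- rep_len(herb_origin, n)
  fc_max <- rep_len(fc_max, n)
  base <- rep_len(base, n)
  structure <- rep_len(structure, n)
  class_tags <- rep_len(class_tags, n)
  fc <- matrix(rep(base, each = 16), nrow = n, byrow = TRUE)
  fc <- t(fc)  # 16 x n
  fc <- t(fc)
  for (i in seq_len(n)) fc[i, 5] <- max(fc_max[i], base[i])
  colnames(fc) <- fc_cols
  cbind(data.frame(compound_id = ids,
                   name = paste0("cmp-", ids),
                   structure = structure,
                   compound_class = compound_class,
                   herb_origin = herb_origin,
                   class_tags = class_tags,
                   stringsAsFactors = FALSE),
        as.data.frame(fc))
}

# Docking scores of the seven predicted critical interactions.
table1_dock <- function() {
  data.frame(
    compound_id = c("MOL39", "MOL67", "MOL18", "MOL43", "MOL43",
                    "MOL43", "MOL10"),
    target_gene = c("CDK1", "MMP9", "PPARD", "PPARG", "PTGS2",
                    "SERPINE1", "PTGS2"),
    gscore = c(-6.125, -6.906, -7.786, -7.534, -8.253, -6.667, -8.29),
    stringsAsFactors = FALSE)
}

# The three known critical interactions.
known_critical <- function() {
  data.frame(
    compound_id = c("MOL14", "MOL52", "MOL17"),
    target_gene = c("TP53", "TP53", "HIF1A"),
    stringsAsFactors = FALSE)
}

# Compound table of the eight critical compounds.  The maximum fold
# changes of MOL43 (2390.64), MOL10 (772.69) and MOL17 (14.35) are the
# reported values; the remaining compounds carry fixture values that
# satisfy the screening threshold and the per-target concentration
# thresholds of their interactions.
critical_compounds <- function() {
  make_compounds(
    ids = c("MOL10", "MOL14", "MOL17", "MOL18", "MOL39", "MOL43",
            "MOL52", "MOL67"),
    compound_class = c("prototype", "prototype", "prototype",
                       "metabolite", "metabolite", "metabolite",
                       "metabolite", "metabolite"),
    herb_origin = c("RA", "RA", "RG", "UNKNOWN", "UNKNOWN", "UNKNOWN",
                    "UNKNOWN", "UNKNOWN"),
    fc_max = c(772.69, 3.1, 14.35, 6.2, 12, 2390.64, 8.4, 25.3))
}

# The critical interaction list as printed: 7 predicted + 3 known.
critical_worked_example <- function() {
  dock <- table1_dock()
  comp <- validate_compound_table(critical_compounds())
  fc <- comp$fc_max[match(c(dock$compound_id,
                            known_critical()$compound_id),
                          comp$compound_id)]
  rbind(
    data.frame(compound_id = dock$compound_id,
               target_gene = dock$target_gene,
               origin = "predicted", gscore = dock$gscore,
               fc_max = fc[seq_len(nrow(dock))],
               stringsAsFactors = FALSE),
    data.frame(compound_id = known_critical()$compound_id,
               target_gene = known_critical()$target_gene,
               origin = "known", gscore = NA_real_,
               fc_max = fc[-seq_len(nrow(dock))],
               stringsAsFactors = FALSE))
}

# Random CTI edge list with exact compound/target/edge cardinalities:
# every compound and every target receives at least one edge.
make_cti_edgelist <- function(n_compounds, n_targets, n_edges, seed = 1) {
  stopifnot(n_edges >= max(n_compounds, n_targets),
            n_edges <= n_compounds * n_targets)
  withr::with_seed(seed, {
    compounds <- sprintf("CMP%03d", seq_len(n_compounds))
    targets <- sprintf("TGT%03d", seq_len(n_targets))
    # cover both partitions, then fill with unused random pairs
    edges <- rbind(
      data.frame(compound_id = compounds,
                 target_gene = sample(targets, n_compounds, replace = TRUE),
                 stringsAsFactors = FALSE),
      data.frame(compound_id = sample(compounds, n_targets, replace = TRUE),
                 target_gene = targets, stringsAsFactors = FALSE))
    key <- paste(edges$compound_id, edges$target_gene)
    edges <- edges[!duplicated(key), ]
    while (nrow(edges) < n_edges) {
      need <- n_edges - nrow(edges)
      cand <- data.frame(
        compound_id = sample(compounds, 2 * need, replace = TRUE),
        target_gene = sample(targets, 2 * need, replace = TRUE),
        stringsAsFactors = FALSE)
      key <- paste(cand$compound_id, cand$target_gene)
      fresh <- !duplicated(key) &
        !(key %in% paste(edges$compound_id, edges$target_gene))
      edges <- rbind(edges, cand[fresh, ][seq_len(min(need, sum(fresh))), ])
    }
    edges$origin <- "predicted"
    rownames(edges) <- NULL
    edges
  })
}

# Small random undirected graph as an igraph object (n <= 10 or so),
# guaranteed at least one edge.
random_small_graph <- function(n, p = 0.4) {
  repeat {
    m <- matrix(stats::runif(n * n) < p, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    if (any(m)) break
  }
  idx <- which(m, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(
    cbind(letters[idx[, 1]], letters[idx[, 2]]), directed = FALSE)
  igraph::add_vertices(g, length(setdiff(letters[1:n], igraph::V(g)$name)),
                       name = setdiff(letters[1:n], igraph::V(g)$name))
}
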