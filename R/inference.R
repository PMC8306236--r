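#' Known compound-target interactions from activity records
#'
#' A measurement supports a known interaction when its Ki, Kd, IC50 or
#' EC50 value is at or below the threshold (default 10 uM).  Surviving
#' measurements are collapsed to unique (compound, target) pairs.
#'
#' @param measurements Activity data.frame (see [read_activity_table()]).
#' @param threshold_uM Activity cutoff in micromolar (kept when
#'   `value_uM <= threshold_uM`).
#' @return Data.frame of unique known interactions with columns
#'   `compound_id`, `target_gene`, `origin` (`"known"`), `score` (`NA`).
#' @export
filter_known_ctis <- function(measurements, threshold_uM = 10) {
  stopifnot(threshold_uM > 0)
  if (any(!is.finite(measurements$value_uM) | measurements$value_uM <= 0)) {
    bad <- which(!is.finite(measurements$value_uM) |
                   measurements$value_uM <= 0)[1]
    stop(sprintf("non-positive activity value at record %d", bad),
         call. = FALSE)
  }
  keep <- measurements$value_uM <= threshold_uM
  pairs <- unique(data.frame(
    compound_id = measurements$compound_id[keep],
    target_gene = toupper(measurements$target_gene[keep]),
    stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$compound_id, pairs$target_gene), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$origin <- rep("known", nrow(pairs))
  pairs$score <- rep(NA_real_, nrow(pairs))
  pairs
}

# Internal node-id prefixes keep the three SDT layers disjoint even if a
# compound id collides with a gene symbol or substructure key.
sdt_id <- function(kind, x) paste0(kind, ":", x)

#' Build a substructure-drug-target diffusion network
#'
#' The network is the union of two bipartite layers sharing the drug
#' nodes: drug-target edges from known interactions and
#' drug-substructure edges from fingerprint membership.  There are no
#' drug-drug, target-target or substructure-target edges.  Substructure
#' keys not attached to any drug are absent by construction.
#'
#' @param known_ctis Data.frame of drug-target edges with columns
#'   `compound_id`, `target_gene` (a global drug-target interaction
#'   edge list, typically including the query compounds' known targets).
#' @param fingerprints Named list mapping drug id to a character vector
#'   of substructure keys.
#' @return An object of class `sdt_network` with elements `drugs`,
#'   `targets`, `substructures` (character vectors), `adjacency`
#'   (sparse symmetric node x node matrix) and `known` (the drug-target
#'   edge data.frame).
#' @export
build_sdt_network <- function(known_ctis, fingerprints) {
  if (is.null(known_ctis) || nrow(known_ctis) == 0) {
    stop("cannot build diffusion network: empty known-interaction list",
         call. = FALSE)
  }
  fingerprints <- fingerprints[vapply(fingerprints, length, integer(1)) > 0]
  drugs <- sort(unique(c(known_ctis$compound_id, names(fingerprints))))
  targets <- sort(unique(toupper(known_ctis$target_gene)))
  no_fp <- setdiff(unique(known_ctis$compound_id), names(fingerprints))
  if (length(no_fp) > 0) {
    warning(sprintf("%d drug(s) have no fingerprint: %s", length(no_fp),
                    paste(utils::head(no_fp, 5), collapse = ", ")),
            call. = FALSE)
  }
  subs <- sort(unique(unlist(fingerprints, use.names = FALSE)))
  nodes <- c(sdt_id("d", drugs), sdt_id("t", targets), sdt_id("s", subs))
  n <- length(nodes)
  node_index <- stats::setNames(seq_len(n), nodes)

  dt_i <- node_index[sdt_id("d", known_ctis$compound_id)]
  dt_j <- node_index[sdt_id("t", toupper(known_ctis$target_gene))]
  fp_drug <- rep(names(fingerprints),
                 vapply(fingerprints, length, integer(1)))
  fp_key <- unlist(fingerprints, use.names = FALSE)
  ds_i <- node_index[sdt_id("d", fp_drug)]
  ds_j <- node_index[sdt_id("s", fp_key)]

  adj <- Matrix::sparseMatrix(i = c(dt_i, ds_i), j = c(dt_j, ds_j),
                              x = 1, dims = c(n, n),
                              dimnames = list(nodes, nodes))
  adj <- methods::as(adj + Matrix::t(adj), "CsparseMatrix")
  adj@x[adj@x > 1] <- 1  # duplicate input edges collapse to simple edges

  known <- unique(data.frame(
    compound_id = known_ctis$compound_id,
    target_gene = toupper(known_ctis$target_gene),
    stringsAsFactors = FALSE))
  structure(list(drugs = drugs, targets = targets, substructures = subs,
                 adjacency = adj, known = known),
            class = "sdt_network")
}

#' @export
print.sdt_network <- function(x, ...) {
  cat(sprintf(
    "substructure-drug-target network: %d drugs, %d targets, %d substructures, %d edges\n",
    length(x$drugs), length(x$targets), length(x$substructures),
    sum(x$adjacency) / 2))
  invisible(x)
}

# Column-stochastic diffusion transition: resource held by node j is
# split among its neighbours i proportionally to deg(i)^alpha (alpha = 0
# gives the equal-split rule of unweighted network-based inference).
sdt_transition <- function(adj, alpha = 0) {
  deg <- Matrix::rowSums(adj)
  if (any(deg == 0)) {
    stop("diffusion network has isolated nodes", call. = FALSE)
  }
  w <- deg^alpha
  m <- Matrix::Diagonal(x = w) %*% adj
  colsum <- Matrix::colSums(m)
  m %*% Matrix::Diagonal(x = 1 / colsum)
}

#' Predict targets by resource diffusion
#'
#' Each query compound starts with one unit of resource on its drug
#' node.  One diffusion round spreads the resource from drugs to their
#' neighbours (targets and substructures) and back to drugs, splitting
#' equally among neighbours (optionally degree-weighted through
#' `alpha`).  After `rounds` rounds a final half-step spreads the
#' resource onto the target layer, whose entries are the prediction
#' scores.  Targets already known for the compound are excluded from
#' the novel ranked list and reported separately.  Ties are broken by
#' score, then lexicographic gene symbol, so rankings are independent
#' of input order.
#'
#' @param network An `sdt_network`.
#' @param compounds Drug ids to score (default: all drugs in the
#'   network).
#' @param top_k Maximum number of novel predicted targets per compound.
#' @param rounds Number of two-phase diffusion rounds (default 2).
#' @param alpha Allocation exponent of the transition (default 0).
#' @return A list with `predictions` (data.frame `compound_id`,
#'   `target_gene`, `score`, `rank`, `origin = "predicted"`) and
#'   `known` (data.frame of the query compounds' known targets).
#' @export
predict_targets <- function(network, compounds = NULL, top_k = 20,
                            rounds = 2, alpha = 0) {
  stopifnot(inherits(network, "sdt_network"), top_k >= 1, rounds >= 1)
  if (is.null(compounds)) compounds <- network$drugs
  missing <- setdiff(compounds, network$drugs)
  if (length(missing) > 0) {
    stop(sprintf("compound(s) absent from diffusion network: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  adj <- network$adjacency
  tr <- sdt_transition(adj, alpha)
  n <- nrow(adj)
  node_names <- rownames(adj)
  drug_rows <- match(sdt_id("d", compounds), node_names)
  f <- Matrix::sparseMatrix(i = drug_rows, j = seq_along(compounds),
                            x = 1, dims = c(n, length(compounds)))
  for (step in seq_len(2L * rounds + 1L)) f <- tr %*% f
  target_rows <- match(sdt_id("t", network$targets), node_names)
  scores <- as.matrix(f[target_rows, , drop = FALSE])
  rownames(scores) <- network$targets
  colnames(scores) <- compounds

  known_by_drug <- split(network$known$target_gene, network$known$compound_id)
  pred_list <- vector("list", length(compounds))
  known_list <- vector("list", length(compounds))
  for (i in seq_along(compounds)) {
    cid <- compounds[i]
    s <- scores[, i]
    known_t <- known_by_drug[[cid]]
    if (is.null(known_t)) known_t <- character(0)
    novel <- s[!(names(s) %in% known_t)]
    novel <- novel[novel > 0]
    if (length(novel) > 0) {
      ord <- order(-novel, names(novel))
      keep <- utils::head(ord, top_k)
      pred_list[[i]] <- data.frame(
        compound_id = cid, target_gene = names(novel)[keep],
        score = unname(novel[keep]), rank = seq_along(keep),
        origin = "predicted", stringsAsFactors = FALSE)
    } else if (sum(adj[drug_rows[i], ]) == 0) {
      warning(sprintf("compound %s has no edges; empty prediction", cid),
              call. = FALSE)
    }
    if (length(known_t) > 0) {
      known_list[[i]] <- data.frame(
        compound_id = cid, target_gene = sort(known_t),
        stringsAsFactors = FALSE)
    }
  }
  list(predictions = do.call(rbind, c(pred_list, list(
         data.frame(compound_id = character(0), target_gene = character(0),
                    score = numeric(0), rank = integer(0),
                    origin = character(0), stringsAsFactors = FALSE)))),
       known = do.call(rbind, c(known_list, list(
         data.frame(compound_id = character(0), target_gene = character(0),
                    stringsAsFactors = FALSE)))))
}

#' Merge known and predicted compound-target interactions
#'
#' Union keyed on the (compound, target) pair.  A pair present in both
#' inputs keeps origin `known`; its prediction score is dropped.
#'
#' @param known Data.frame with columns `compound_id`, `target_gene`
#'   (known interactions).
#' @param predicted Data.frame with columns `compound_id`,
#'   `target_gene`, `score` (predicted interactions).
#' @return Data.frame with columns `compound_id`, `target_gene`,
#'   `origin`, `score`, sorted by compound then target; the numbers of
#'   known and predicted records are attached as attribute `counts`.
#' @export
merge_cti <- function(known, predicted) {
  known_pairs <- unique(paste(known$compound_id, known$target_gene,
                              sep = "\r"))
  k <- data.frame(compound_id = known$compound_id,
                  target_gene = known$target_gene,
                  origin = "known", score = NA_real_,
                  stringsAsFactors = FALSE)
  k <- k[!duplicated(paste(k$compound_id, k$target_gene, sep = "\r")), ,
         drop = FALSE]
  p <- data.frame(compound_id = predicted$compound_id,
                  target_gene = predicted$target_gene,
                  origin = "predicted",
                  score = if ("score" %in% names(predicted))
                    predicted$score else NA_real_,
                  stringsAsFactors = FALSE)
  p <- p[!duplicated(paste(p$compound_id, p$target_gene, sep = "\r")), ,
         drop = FALSE]
  p <- p[!(paste(p$compound_id, p$target_gene, sep = "\r") %in%
             known_pairs), , drop = FALSE]
  out <- rbind(k, p)
  out <- out[order(out$compound_id, out$target_gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(known = nrow(k), predicted = nrow(p),
                           total = nrow(out))
  out
}
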