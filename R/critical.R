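#' Concentration filter on compound-target interactions
#'
#' Restricts interactions with selected high-degree targets to compounds
#' with sufficient in-vivo exposure.  For metabolites interacting with a
#' target that has a configured fold-change threshold, the interaction
#' is kept only when the compound's maximum fold change is strictly
#' greater than the threshold.  Prototype-compound interactions, and
#' interactions with targets that have no configured threshold, pass
#' unchanged.
#'
#' @param ctis Data.frame of interactions (`compound_id`, `target_gene`,
#'   optionally `origin`), typically already restricted to hub targets.
#' @param compounds Compound table supplying `compound_class` and
#'   `fc_max`.
#' @param thresholds Named numeric vector target gene -> fold-change
#'   threshold (default `c(PPARG = 10, PTGS2 = 10, PPARD = 5,
#'   SERPINE1 = 5)`).
#' @return The surviving rows of `ctis`, with a `fc_max` column joined
#'   in.
#' @export
concentration_filter <- function(ctis, compounds,
                                 thresholds = c(PPARG = 10, PTGS2 = 10,
                                                PPARD = 5, SERPINE1 = 5)) {
  stopifnot(all(thresholds > 0))
  idx <- match(ctis$compound_id, compounds$compound_id)
  if (any(is.na(idx))) {
    stop(sprintf("interaction references unknown compound: %s",
                 ctis$compound_id[which(is.na(idx))[1]]), call. = FALSE)
  }
  cls <- compounds$compound_class[idx]
  fc_max <- compounds$fc_max[idx]
  thr <- thresholds[ctis$target_gene]
  needs_filter <- cls == "metabolite" & !is.na(thr)
  missing_fc <- needs_filter & is.na(fc_max)
  if (any(missing_fc)) {
    stop(sprintf("metabolite without fold-change data: %s",
                 ctis$compound_id[which(missing_fc)[1]]), call. = FALSE)
  }
  keep <- !needs_filter | fc_max > thr
  out <- ctis[keep, , drop = FALSE]
  out$fc_max <- fc_max[keep]
  rownames(out) <- NULL
  out
}

#' Median split of docking scores
#'
#' Flags each docking record as strong or weak relative to the median of
#' all supplied scores.  Under the default rule `below_median`, a score
#' strictly below (more negative than) the median is strong - the
#' convention under which lower docking scores indicate stronger
#' binding.  Records equal to the median are weak.
#'
#' @param dock_table Data.frame with columns `compound_id`,
#'   `target_gene`, `gscore`.
#' @param rule `"below_median"` (default) or `"above_median"`.
#' @return The input with a logical `strong` column; the median is
#'   attached as attribute `median`.
#' @export
gscore_median_split <- function(dock_table,
                                rule = c("below_median", "above_median")) {
  rule <- match.arg(rule)
  if (is.null(dock_table) || nrow(dock_table) == 0) {
    stop("empty docking table", call. = FALSE)
  }
  med <- stats::median(dock_table$gscore)
  dock_table$strong <- if (rule == "below_median") {
    dock_table$gscore < med
  } else {
    dock_table$gscore > med
  }
  attr(dock_table, "median") <- med
  dock_table
}

# Pareto front of (minimize gscore, maximize fc_max): a candidate is
# dominated when another is no worse in both and better in one.
pareto_front <- function(gscore, fc_max) {
  n <- length(gscore)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    dominated <- any(gscore <= gscore[i] & fc_max >= fc_max[i] &
                       (gscore < gscore[i] | fc_max > fc_max[i]))
    if (dominated) keep[i] <- FALSE
  }
  keep
}

#' Select critical compound-target interactions
#'
#' Two channels per target: (1) among the known interactions of a
#' target, the one whose compound has the largest maximum fold change is
#' reserved; (2) among the predicted interactions of a target, the
#' candidate with the lower docking score and the greater fold change is
#' retained.  When the two orderings conflict in channel (2), the
#' default policy restricts to the Pareto front of (lower score, higher
#' fold change) and then prefers the lower score; remaining ties prefer
#' the higher fold change, then the lexicographically smaller compound
#' id.  A target may contribute one interaction from each channel.
#'
#' @param known_ctis Data.frame of known interactions (`compound_id`,
#'   `target_gene`).
#' @param predicted_ctis Data.frame of predicted interactions.
#' @param dock_table Docking scores covering every predicted candidate.
#' @param compounds Compound table supplying `fc_max`.
#' @param tie_policy `"pareto_gscore_first"` (default), `"gscore_only"`,
#'   `"fcmax_only"`, or `"pareto_all"`, which keeps every candidate on
#'   the Pareto front of (lower score, higher fold change) - the only
#'   reading under which a target may retain two predicted interactions
#'   whose score and fold-change orders conflict.
#' @return Data.frame of critical interactions with columns
#'   `compound_id`, `target_gene`, `origin`, `gscore` (`NA` for known),
#'   `fc_max`.
#' @export
select_critical <- function(known_ctis, predicted_ctis, dock_table,
                            compounds,
                            tie_policy = c("pareto_gscore_first",
                                           "gscore_only", "fcmax_only",
                                           "pareto_all")) {
  tie_policy <- match.arg(tie_policy)
  fc_of <- function(ids) compounds$fc_max[match(ids, compounds$compound_id)]
  out <- list()

  if (!is.null(known_ctis) && nrow(known_ctis) > 0) {
    known_ctis$fc_max <- fc_of(known_ctis$compound_id)
    for (tg in sort(unique(known_ctis$target_gene))) {
      cand <- known_ctis[known_ctis$target_gene == tg, , drop = FALSE]
      cand <- cand[order(-cand$fc_max, cand$compound_id), , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        compound_id = cand$compound_id[1], target_gene = tg,
        origin = "known", gscore = NA_real_, fc_max = cand$fc_max[1],
        stringsAsFactors = FALSE)
    }
  }

  if (!is.null(predicted_ctis) && nrow(predicted_ctis) > 0) {
    key <- paste(predicted_ctis$compound_id, predicted_ctis$target_gene,
                 sep = "\r")
    dkey <- paste(dock_table$compound_id, dock_table$target_gene,
                  sep = "\r")
    hit <- match(key, dkey)
    if (any(is.na(hit))) {
      miss <- which(is.na(hit))[1]
      stop(sprintf("predicted candidate without docking score: %s - %s",
                   predicted_ctis$compound_id[miss],
                   predicted_ctis$target_gene[miss]), call. = FALSE)
    }
    predicted_ctis$gscore <- dock_table$gscore[hit]
    predicted_ctis$fc_max <- fc_of(predicted_ctis$compound_id)
    for (tg in sort(unique(predicted_ctis$target_gene))) {
      cand <- predicted_ctis[predicted_ctis$target_gene == tg, ,
                             drop = FALSE]
      if (tie_policy %in% c("pareto_gscore_first", "pareto_all")) {
        cand <- cand[pareto_front(cand$gscore, cand$fc_max), ,
                     drop = FALSE]
        cand <- cand[order(cand$gscore, -cand$fc_max, cand$compound_id), ,
                     drop = FALSE]
      } else if (tie_policy == "gscore_only") {
        cand <- cand[order(cand$gscore, -cand$fc_max, cand$compound_id), ,
                     drop = FALSE]
      } else {
        cand <- cand[order(-cand$fc_max, cand$gscore, cand$compound_id), ,
                     drop = FALSE]
      }
      keep <- if (tie_policy == "pareto_all") seq_len(nrow(cand)) else 1L
      out[[length(out) + 1]] <- data.frame(
        compound_id = cand$compound_id[keep], target_gene = tg,
        origin = "predicted", gscore = cand$gscore[keep],
        fc_max = cand$fc_max[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    warning("no critical interactions selected", call. = FALSE)
    return(data.frame(compound_id = character(0),
                      target_gene = character(0), origin = character(0),
                      gscore = numeric(0), fc_max = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$target_gene, res$origin, res$compound_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the critical bipartite network
#'
#' @param critical_ctis Output of [select_critical()].
#' @param compounds Compound table (labels and fold changes for node
#'   attributes).
#' @return An undirected bipartite igraph with vertex attributes `kind`,
#'   `label`, `fc_max` and edge attributes `origin`, `gscore`.
#' @export
build_critical_network <- function(critical_ctis, compounds) {
  if (is.null(critical_ctis) || nrow(critical_ctis) == 0) {
    stop("empty critical interaction list", call. = FALSE)
  }
  comp <- sort(unique(critical_ctis$compound_id))
  targ <- sort(unique(critical_ctis$target_gene))
  lab <- compound_labels(compounds)[comp]
  lab[is.na(lab)] <- "MC"
  fc <- compounds$fc_max[match(comp, compounds$compound_id)]
  vertices <- data.frame(
    name = c(comp, targ),
    kind = c(rep("compound", length(comp)), rep("target", length(targ))),
    label = c(unname(lab), rep("target", length(targ))),
    fc_max = c(fc, rep(NA_real_, length(targ))),
    type = c(rep(FALSE, length(comp)), rep(TRUE, length(targ))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = critical_ctis$compound_id,
               to = critical_ctis$target_gene,
               origin = critical_ctis$origin,
               gscore = critical_ctis$gscore,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = vertices)
  stopifnot(igraph::is_bipartite(g))
  g
}

#' Cross-docking consistency of selected interactions
#'
#' For each selected predicted interaction, checks whether its compound
#' attains the minimum (best) docking score among all compounds docked
#' to that target in the cross-docking matrix.
#'
#' @param dock_matrix Long-form data.frame `compound_id`, `target_gene`,
#'   `gscore` covering the cross-docking runs (may be partial).
#' @param selected Data.frame of selected predicted interactions
#'   (`compound_id`, `target_gene`).
#' @return Data.frame per selected target: selected and best compound,
#'   their scores and a `consistent` flag; the overall fraction of
#'   consistent targets is attached as attribute `fraction`.
#' @export
cross_dock_consistency <- function(dock_matrix, selected) {
  rows <- lapply(seq_len(nrow(selected)), function(i) {
    tg <- selected$target_gene[i]
    cid <- selected$compound_id[i]
    col <- dock_matrix[dock_matrix$target_gene == tg, , drop = FALSE]
    sel_g <- col$gscore[match(cid, col$compound_id)]
    best <- col[order(col$gscore, col$compound_id), , drop = FALSE][1, ]
    data.frame(target_gene = tg, selected_compound = cid,
               selected_gscore = sel_g,
               best_compound = best$compound_id,
               best_gscore = best$gscore,
               consistent = !is.na(sel_g) & sel_g <= best$gscore,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fraction") <- mean(out$consistent)
  out
}
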