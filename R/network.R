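#' Intersect predicted/known targets with a disease gene list
#'
#' @param cti_targets Character vector of target gene symbols.
#' @param disease_genes Character vector of disease-associated gene
#'   symbols.
#' @return Character vector of overlapping symbols (sorted).
#' @export
map_disease_genes <- function(cti_targets, disease_genes) {
  overlap <- sort(intersect(normalize_gene_symbols(cti_targets),
                            normalize_gene_symbols(disease_genes)))
  if (length(overlap) == 0) {
    stop("empty intersection: no disease-relevant targets", call. = FALSE)
  }
  overlap
}

#' Build the compound-disease-target bipartite network
#'
#' Keeps only interactions whose target belongs to the disease overlap,
#' drops compounds left without any edge, and labels compound nodes by
#' herb class (`RAC`, `RGC`, `RAGC`, `MC`).  Edges carry their origin
#' (`known`/`predicted`).
#'
#' @param cti_table Merged interaction data.frame with columns
#'   `compound_id`, `target_gene`, `origin`.
#' @param overlap_targets Disease-relevant target symbols (edges to
#'   other targets are discarded).
#' @param labels Named character vector compound id -> label (see
#'   [compound_labels()]); unlabeled compounds default to `MC` with a
#'   warning.
#' @return An undirected bipartite [igraph::igraph] object with vertex
#'   attributes `kind` (`compound`/`target`), `label` and `type`
#'   (logical bipartite indicator, `TRUE` for targets) and edge
#'   attribute `origin`.
#' @export
build_clft_network <- function(cti_table, overlap_targets,
                               labels = character()) {
  edges <- cti_table[cti_table$target_gene %in% overlap_targets, ,
                     drop = FALSE]
  edges <- edges[!duplicated(paste(edges$compound_id, edges$target_gene,
                                   sep = "\r")), , drop = FALSE]
  if (nrow(edges) == 0) {
    stop("no edges remain after disease-gene filtering", call. = FALSE)
  }
  compounds <- sort(unique(edges$compound_id))
  targets <- sort(unique(edges$target_gene))
  clash <- intersect(compounds, targets)
  if (length(clash) > 0) {
    stop(sprintf("compound ids collide with target symbols: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }
  lab <- labels[compounds]
  unlabeled <- is.na(lab) | !nzchar(lab)
  if (any(unlabeled)) {
    warning(sprintf("%d unlabeled compound(s) default to MC",
                    sum(unlabeled)), call. = FALSE)
    lab[unlabeled] <- "MC"
  }
  vertices <- data.frame(
    name = c(compounds, targets),
    kind = c(rep("compound", length(compounds)),
             rep("target", length(targets))),
    label = c(unname(lab), rep("target", length(targets))),
    type = c(rep(FALSE, length(compounds)), rep(TRUE, length(targets))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$compound_id, to = edges$target_gene,
               origin = if ("origin" %in% names(edges)) edges$origin
                        else "predicted",
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = vertices)
  stopifnot(igraph::is_bipartite(g))
  g
}

#' Per-node degrees of a network
#'
#' @param network An igraph object.
#' @return Data.frame with columns `node`, `kind` (if present as a
#'   vertex attribute) and `degree`, sorted by decreasing degree then
#'   lexicographic node name.
#' @export
degree_table <- function(network) {
  deg <- igraph::degree(network)
  out <- data.frame(node = names(deg), degree = unname(deg),
                    stringsAsFactors = FALSE)
  if ("kind" %in% igraph::vertex_attr_names(network)) {
    out$kind <- igraph::V(network)$kind
    out <- out[, c("node", "kind", "degree")]
  }
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network to GraphML or SIF
#'
#' GraphML round-trips all node and edge attributes; SIF carries the
#' topology plus the edge type only (`node<TAB>type<TAB>node`, one edge
#' per line), where the type is the `origin` edge attribute when present
#' and `pp` otherwise.
#'
#' @param network An igraph object.
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "sif")) {
  if (length(format) == 1 && !format %in% c("graphml", "sif")) {
    stop(sprintf("unknown network format: %s", format), call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    ends <- igraph::as_edgelist(network)
    type <- if ("origin" %in% igraph::edge_attr_names(network)) {
      igraph::E(network)$origin
    } else {
      rep("pp", nrow(ends))
    }
    writeLines(paste(ends[, 1], type, ends[, 2], sep = "\t"), path)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
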