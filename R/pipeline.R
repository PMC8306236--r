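stage_call <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline on in-memory inputs
#'
#' Executes all stages in order on a bundle of in-memory inputs (the
#' shape produced by [gen_bundle()]): compound screen, known-interaction
#' filter, diffusion target prediction, known/predicted merge,
#' disease-gene intersection and bipartite network, PPI hub scoring,
#' pathway over-representation, and critical-interaction selection.
#'
#' @param bundle List with elements `compounds`, `fingerprints`,
#'   `activities`, `dti`, `disease_genes`, `ppi`, `pathways`, `dock`.
#' @param config A [pipeline_config()].
#' @return A list of stage results: `screen`, `known`, `predicted`,
#'   `merged`, `overlap`, `clft`, `degrees`, `ppi`, `ranks`, `scores`,
#'   `hubs`, `enrichment`, `critical_targets`, `critical`,
#'   `critical_network`, `dock_split`, `cross_dock`.
#' @export
run_pipeline_stages <- function(bundle, config = pipeline_config()) {
  res <- list(config = config)

  res$screen <- stage_call("screen", screen_compounds(
    bundle$compounds, config$fc_screen_threshold, config$exclusion_tags))
  screened <- res$screen$table

  res$known <- stage_call("known_cti", {
    k <- filter_known_ctis(bundle$activities, config$activity_threshold_uM)
    k[k$compound_id %in% res$screen$retained, , drop = FALSE]
  })

  res$predicted <- stage_call("predict", {
    edges <- rbind(
      bundle$dti[, c("compound_id", "target_gene")],
      res$known[, c("compound_id", "target_gene")])
    sdt <- suppressWarnings(build_sdt_network(edges, bundle$fingerprints))
    query <- intersect(res$screen$retained, sdt$drugs)
    if (length(query) == 0) stop("no screened compound is predictable")
    predict_targets(sdt, query, top_k = config$top_k_predictions,
                    rounds = config$diffusion_rounds,
                    alpha = config$allocation_exponent)
  })

  res$merged <- stage_call("merge",
    merge_cti(res$known, res$predicted$predictions))

  res$overlap <- stage_call("network", map_disease_genes(
    unique(res$merged$target_gene), bundle$disease_genes))
  res$clft <- stage_call("network", build_clft_network(
    res$merged, res$overlap, compound_labels(screened)))
  res$degrees <- stage_call("network", degree_table(res$clft))

  res$hubs <- stage_call("hubs", {
    net_targets <- igraph::V(res$clft)$name[igraph::V(res$clft)$kind ==
                                              "target"]
    ppi_edges <- bundle$ppi[bundle$ppi$gene_a %in% net_targets &
                              bundle$ppi$gene_b %in% net_targets, ,
                            drop = FALSE]
    if (nrow(ppi_edges) == 0) stop("no protein-protein interactions")
    g <- ppi_graph(ppi_edges)
    res$ppi <- g
    res$ranks <- centrality_rank_table(
      g, seed = config$seed, epc_replicates = config$epc_replicates,
      epc_edge_prob = config$epc_edge_prob)
    res$scores <- aggregate_score(res$ranks)
    counts <- compound_counts_per_target(
      res$merged[res$merged$target_gene %in% net_targets, , drop = FALSE])
    suppressWarnings(select_hubs(res$scores, counts, config$manual_hubs))
  })

  res$enrichment <- stage_call("enrich", {
    hub_genes <- res$hubs$node[res$hubs$hub]
    if (length(hub_genes) == 0) stop("no hub genes selected")
    enr <- suppressWarnings(hypergeom_enrich(
      hub_genes, bundle$pathways, fdr_threshold = config$fdr_threshold))
    curate_pathways(enr, config$exclude_patterns)
  })

  res$critical <- stage_call("select", {
    retained <- res$enrichment$pathway[res$enrichment$retained]
    retained_genes <- unique(unlist(bundle$pathways[retained],
                                    use.names = FALSE))
    hub_genes <- res$hubs$node[res$hubs$hub]
    crit_targets <- intersect(hub_genes, retained_genes)
    if (length(crit_targets) == 0) stop("no critical targets")
    res$critical_targets <- crit_targets
    ctis <- res$merged[res$merged$target_gene %in% crit_targets, ,
                       drop = FALSE]
    ctis <- concentration_filter(ctis, screened,
                                 config$fc_max_thresholds)
    known <- ctis[ctis$origin == "known", , drop = FALSE]
    predicted <- ctis[ctis$origin == "predicted", , drop = FALSE]
    if (nrow(predicted) > 0) {
      res$dock_split <- gscore_median_split(
        bundle$dock[paste(bundle$dock$compound_id,
                          bundle$dock$target_gene) %in%
                      paste(predicted$compound_id, predicted$target_gene),
                    , drop = FALSE],
        rule = config$gscore_strong_rule)
    }
    select_critical(known, predicted, bundle$dock, screened,
                    tie_policy = config$tie_policy)
  })

  res$critical_network <- stage_call("select",
    build_critical_network(res$critical, screened))

  sel_pred <- res$critical[res$critical$origin == "predicted", ,
                           drop = FALSE]
  if (nrow(sel_pred) > 0) {
    res$cross_dock <- stage_call("select",
      cross_dock_consistency(bundle$dock, sel_pred))
  }
  res
}

#' Read a bundle of pipeline input files
#'
#' @param paths Named character vector or list with elements
#'   `compounds`, `fingerprints`, `activities`, `dti`, `disease_genes`,
#'   `ppi`, `pathways`, `dock`.
#' @return An in-memory bundle (see [run_pipeline_stages()]).
#' @export
read_bundle <- function(paths) {
  needed <- c("compounds", "fingerprints", "activities", "dti",
              "disease_genes", "ppi", "pathways", "dock")
  missing <- setdiff(needed, names(paths))
  if (length(missing) > 0) {
    stop(sprintf("missing input path(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (p in unlist(paths[needed])) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p),
                              call. = FALSE)
  }
  list(compounds = read_compound_table(paths[["compounds"]]),
       fingerprints = read_fingerprints(paths[["fingerprints"]]),
       activities = read_activity_table(paths[["activities"]]),
       dti = read_cti_table(paths[["dti"]]),
       disease_genes = read_gene_list(paths[["disease_genes"]]),
       ppi = read_ppi_edges(paths[["ppi"]]),
       pathways = read_gmt(paths[["pathways"]]),
       dock = read_dock_table(paths[["dock"]]))
}

#' Run the pipeline on input files and write stage outputs
#'
#' Reads the seven inputs, runs every stage (see
#' [run_pipeline_stages()]) and writes six stage outputs plus a JSON
#' manifest into `out_dir`.  Every tabular output embeds the
#' configuration hash and seed in `#` header comments; re-running with
#' the same inputs, configuration and seed is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param inputs Named paths (see [read_bundle()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the stage-result list with the manifest attached
#'   as `manifest`.
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  bundle <- read_bundle(inputs)
  res <- run_pipeline_stages(bundle, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- output_comments(config)

  screen_out <- res$screen$table
  removed <- data.frame(compound_id = names(res$screen$removed),
                        removal_reason = unname(res$screen$removed),
                        stringsAsFactors = FALSE)
  outputs <- c(
    screen = file.path(out_dir, "01_screen.tsv"),
    cti = file.path(out_dir, "02_cti.tsv"),
    network = file.path(out_dir, "03_network.graphml"),
    hubs = file.path(out_dir, "04_hubs.tsv"),
    enrichment = file.path(out_dir, "05_enrichment.tsv"),
    critical = file.path(out_dir, "06_critical.graphml"))
  write_tsv(screen_out, outputs["screen"], comments = hdr)
  write_tsv(removed, file.path(out_dir, "01_screen_removed.tsv"),
            comments = hdr)
  write_tsv(res$merged, outputs["cti"], comments = hdr)
  export_network(res$clft, outputs["network"], "graphml")
  export_network(res$clft, file.path(out_dir, "03_network.sif"), "sif")
  write_tsv(res$degrees, file.path(out_dir, "03_degrees.tsv"),
            comments = hdr)
  hubs_out <- merge(res$ranks, res$hubs, by = "node", sort = TRUE)
  write_tsv(hubs_out, outputs["hubs"], comments = hdr)
  write_tsv(res$enrichment, outputs["enrichment"], comments = hdr)
  export_network(res$critical_network, outputs["critical"], "graphml")
  export_network(res$critical_network,
                 file.path(out_dir, "06_critical.sif"), "sif")
  write_tsv(res$critical, file.path(out_dir, "06_critical.tsv"),
            comments = hdr)

  manifest <- list(
    package = "herbnet",
    version = as.character(utils::packageVersion("herbnet")),
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    inputs = as.list(unlist(inputs)),
    outputs = as.list(unname(outputs)),
    counts = list(
      compounds_retained = length(res$screen$retained),
      known_ctis = nrow(res$known),
      merged_ctis = nrow(res$merged),
      disease_overlap_targets = length(res$overlap),
      network_nodes = igraph::vcount(res$clft),
      network_edges = igraph::ecount(res$clft),
      hub_genes = sum(res$hubs$hub),
      significant_pathways = sum(res$enrichment$significant),
      retained_pathways = sum(res$enrichment$retained),
      critical_interactions = nrow(res$critical)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
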