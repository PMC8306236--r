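#' Pipeline configuration
#'
#' Bundles every tunable parameter of the pipeline.  Defaults follow the
#' published workflow: compounds are kept when their maximum fold change
#' over the 16 post-dose periods is at least 2; a compound-target
#' interaction counts as known when a Ki/Kd/IC50/EC50 value is at or
#' below 10 uM; the top 20 diffusion-predicted targets are retained per
#' compound; pathways are significant below an FDR of 0.05; and the
#' concentration filter applies per-target fold-change thresholds to
#' metabolites (10 for PPARG and PTGS2, 5 for PPARD and SERPINE1).
#'
#' @param fc_screen_threshold Fold-change screening threshold (a compound
#'   is removed when every observed period is strictly below it).
#' @param activity_threshold_uM Activity cutoff in micromolar for known
#'   compound-target interactions.
#' @param top_k_predictions Predicted targets kept per compound.
#' @param fdr_threshold Benjamini-Hochberg significance cutoff.
#' @param fc_max_thresholds Named numeric vector mapping target gene to
#'   the metabolite fold-change threshold used by the concentration
#'   filter (strict `>`).  Targets absent from the map pass unchanged.
#' @param manual_hubs Gene symbols force-included as hubs regardless of
#'   the score criterion (curated additions).
#' @param exclusion_tags Curation tags whose presence removes a compound
#'   at the screening stage (e.g. `amino_acid`, `short_aliphatic`).
#' @param exclude_patterns Glob patterns of pathway names removed by the
#'   curation step after enrichment (e.g. `"*cancer*"`).
#' @param diffusion_rounds Number of two-phase diffusion rounds.
#' @param allocation_exponent Degree-weighting exponent of the diffusion
#'   transition; 0 gives unweighted network-based inference.
#' @param epc_replicates Monte-Carlo replicates for the edge-percolated
#'   component centrality.
#' @param epc_edge_prob Edge retention probability per percolation
#'   replicate.
#' @param gscore_strong_rule `below_median` (more negative docking score
#'   is stronger, the convention of the reported results) or
#'   `above_median`.
#' @param tie_policy Resolution of the joint docking-score /
#'   fold-change criterion for predicted critical interactions.
#' @param seed Integer seed recorded in every output header and used for
#'   all stochastic stages.
#' @return An object of class `herbnet_config` (a named list).
#' @export
pipeline_config <- function(fc_screen_threshold = 2,
                            activity_threshold_uM = 10,
                            top_k_predictions = 20,
                            fdr_threshold = 0.05,
                            fc_max_thresholds = c(PPARG = 10, PTGS2 = 10,
                                                  PPARD = 5, SERPINE1 = 5),
                            manual_hubs = character(),
                            exclusion_tags = character(),
                            exclude_patterns = character(),
                            diffusion_rounds = 2,
                            allocation_exponent = 0,
                            epc_replicates = 1000,
                            epc_edge_prob = 0.5,
                            gscore_strong_rule = c("below_median",
                                                   "above_median"),
                            tie_policy = c("pareto_gscore_first",
                                           "gscore_only", "fcmax_only",
                                           "pareto_all"),
                            seed = 1L) {
  gscore_strong_rule <- match.arg(gscore_strong_rule)
  tie_policy <- match.arg(tie_policy)
  stopifnot(fc_screen_threshold > 0, activity_threshold_uM > 0,
            top_k_predictions >= 1, fdr_threshold > 0,
            all(fc_max_thresholds > 0), diffusion_rounds >= 1,
            epc_replicates >= 1, epc_edge_prob > 0, epc_edge_prob <= 1)
  cfg <- list(
    fc_screen_threshold = fc_screen_threshold,
    activity_threshold_uM = activity_threshold_uM,
    top_k_predictions = as.integer(top_k_predictions),
    fdr_threshold = fdr_threshold,
    fc_max_thresholds = fc_max_thresholds,
    manual_hubs = toupper(manual_hubs),
    exclusion_tags = exclusion_tags,
    exclude_patterns = exclude_patterns,
    diffusion_rounds = as.integer(diffusion_rounds),
    allocation_exponent = allocation_exponent,
    epc_replicates = as.integer(epc_replicates),
    epc_edge_prob = epc_edge_prob,
    gscore_strong_rule = gscore_strong_rule,
    tie_policy = tie_policy,
    seed = as.integer(seed))
  class(cfg) <- "herbnet_config"
  cfg
}

#' @rdname pipeline_config
#' @param path Path to a YAML configuration file whose keys match the
#'   arguments of [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configuration requires the 'yaml' package",
         call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$fc_max_thresholds)) {
    vals$fc_max_thresholds <- unlist(vals$fc_max_thresholds)
  }
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param config A `herbnet_config` object.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

# Metadata comment lines embedded in every stage output.
output_comments <- function(config) {
  c(sprintf("herbnet %s", as.character(utils::packageVersion("herbnet"))),
    sprintf("config_hash=%s", config_hash(config)),
    sprintf("seed=%d", config$seed))
}
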