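#' Specification of a synthetic input bundle
#'
#' Defines the statistical structure of every generated pipeline input.
#' Defaults emulate the published study conditions: 68 compounds (17
#' prototypes, 51 metabolites) with 16-period fold-change series, a
#' drug-target interaction library for diffusion prediction, a disease
#' gene list, a 48-node / 71-edge protein-protein interaction network
#' with planted hubs, pathway annotations with one planted enriched
#' pathway, and a docking-score table with planted strong binders.
#'
#' @param seed Integer seed (mandatory; the bundle is a deterministic
#'   function of the spec).
#' @param n_prototype,n_metabolite Compound counts by class.
#' @param n_effective Number of planted "absorbed" compounds whose
#'   fold-change series contains spiked periods; all other compounds
#'   fail the screen.
#' @param fc_threshold Screening threshold the spikes are planted
#'   against.
#' @param fc_baseline_sdlog Log-sd of the lognormal baseline fold
#'   changes (baselines are capped strictly below the threshold).
#' @param fc_spike_meanlog,fc_spike_sdlog Lognormal parameters of the
#'   multiplicative absorption spikes (floored at twice the threshold).
#' @param fc_missing_rate Probability that a period is unmeasured.
#' @param n_no_structure,n_excluded_class Among the non-effective
#'   compounds, how many are additionally removed for missing structure
#'   or for a curated exclusion tag.
#' @param fingerprint_dict_size,bits_per_compound Substructure-key
#'   dictionary size and keys per molecule.
#' @param fingerprint_noise Per-key drop probability when a compound's
#'   fingerprint is derived from its library donor drug.
#' @param n_library_drugs,n_targets Size of the drug-target interaction
#'   library; each library drug receives 2-5 targets.
#' @param n_disease_targets Number of library targets included in the
#'   disease gene list (planted hubs always are).
#' @param n_disease_decoys Disease genes that are not library targets.
#' @param n_ppi_nodes,n_ppi_edges PPI network size.
#' @param n_planted_hubs,hub_degree_boost Planted hub count and extra
#'   edges wired to each hub.
#' @param n_pathways,pathway_size_range Pathway annotation shape; every
#'   target belongs to at least one pathway.
#' @param enriched_pathway_extras Non-hub PPI genes added to the planted
#'   enriched pathway (0 keeps the planted set at the hub module, the
#'   strongest detectable signal).
#' @param gscore_mean,gscore_sd Normal model of docking scores.
#' @param gscore_planted_gap Margin by which a planted strong binder
#'   beats the best competing score at its target.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed,
                            n_prototype = 17,
                            n_metabolite = 51,
                            n_effective = 40,
                            fc_threshold = 2,
                            fc_baseline_sdlog = 0.2,
                            fc_spike_meanlog = log(10),
                            fc_spike_sdlog = 1.2,
                            fc_missing_rate = 0.05,
                            n_no_structure = 4,
                            n_excluded_class = 4,
                            fingerprint_dict_size = 120,
                            bits_per_compound = 8,
                            fingerprint_noise = 0.1,
                            n_library_drugs = 150,
                            n_targets = 300,
                            n_disease_targets = 95,
                            n_disease_decoys = 1097,
                            n_ppi_nodes = 48,
                            n_ppi_edges = 71,
                            n_planted_hubs = 3,
                            hub_degree_boost = 8,
                            n_pathways = 15,
                            pathway_size_range = c(8, 25),
                            enriched_pathway_extras = 0,
                            gscore_mean = -5,
                            gscore_sd = 1,
                            gscore_planted_gap = 1.5) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  n_compounds <- n_prototype + n_metabolite
  stopifnot(n_prototype > 0, n_metabolite > 0,
            n_effective > 0, n_effective <= n_compounds,
            n_no_structure + n_excluded_class <= n_compounds - n_effective,
            fingerprint_dict_size > bits_per_compound,
            n_disease_targets <= n_targets,
            n_ppi_nodes <= n_disease_targets,
            n_ppi_edges <= n_ppi_nodes * (n_ppi_nodes - 1) / 2,
            n_planted_hubs < n_ppi_nodes,
            n_pathways >= 2, gscore_planted_gap > 0)
  spec <- as.list(environment())
  spec$n_compounds <- n_compounds
  class(spec) <- "simulation_spec"
  spec
}

# Run expr under a local RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Plausible-looking synthetic SMILES; no chemistry is implied.
synth_smiles <- function(n) {
  vapply(seq_len(n), function(i) {
    paste0("C", paste(sample(c("C", "O", "N", "C(=O)", "c1ccccc1"),
                             sample(3:6, 1), replace = TRUE),
                      collapse = ""))
  }, character(1))
}

#' Generate a preferential-attachment PPI network with planted hubs
#'
#' Grows a tree by preferential attachment over the supplied nodes, then
#' spends the remaining edge budget first on wiring each planted hub to
#' additional non-neighbours (`boost` edges per hub) and then on random
#' degree-proportional extra edges, so the requested node and edge
#' counts are met exactly.
#'
#' @param nodes Character vector of node names.
#' @param n_edges Total number of edges (at most `choose(n, 2)`).
#' @param hubs Node names to plant as hubs (subset of `nodes`).
#' @param boost Extra edges wired to each planted hub.
#' @param seed Integer seed.
#' @return A list with `edges` (data.frame `gene_a`, `gene_b`) and
#'   `hubs`.
#' @export
gen_ppi_with_hubs <- function(nodes, n_edges, hubs = character(),
                              boost = 8, seed = 1L) {
  n <- length(nodes)
  stopifnot(n >= 2, n_edges <= n * (n - 1) / 2,
            all(hubs %in% nodes), length(hubs) < n)
  with_seed(seed, {
    adj <- matrix(FALSE, n, n)
    edge_a <- integer(0); edge_b <- integer(0)
    add_edge <- function(i, j) {
      adj[i, j] <<- TRUE; adj[j, i] <<- TRUE
      edge_a <<- c(edge_a, i); edge_b <<- c(edge_b, j)
    }
    deg <- numeric(n)
    # preferential-attachment tree over a random arrival order
    order_in <- sample.int(n)
    tree_edges <- min(n - 1, n_edges)
    for (k in 2:(tree_edges + 1)) {
      v <- order_in[k]
      prev <- order_in[seq_len(k - 1)]
      w <- prev[sample.int(k - 1, 1, prob = deg[prev] + 1)]
      add_edge(v, w)
      deg[v] <- deg[v] + 1; deg[w] <- deg[w] + 1
      if (length(edge_a) >= n_edges) break
    }
    budget <- n_edges - length(edge_a)
    hub_idx <- match(hubs, nodes)
    if (budget > 0 && length(hub_idx) > 0 && boost > 0) {
      for (rep in seq_len(boost)) {
        for (h in hub_idx) {
          if (budget == 0) break
          free <- which(!adj[h, ] & seq_len(n) != h)
          if (length(free) == 0) next
          w <- free[sample.int(length(free), 1)]
          add_edge(h, w)
          deg[h] <- deg[h] + 1; deg[w] <- deg[w] + 1
          budget <- budget - 1
        }
        if (budget == 0) break
      }
    }
    while (budget > 0) {
      i <- sample.int(n, 1, prob = deg + 1)
      free <- which(!adj[i, ] & seq_len(n) != i)
      if (length(free) == 0) next
      j <- free[sample.int(length(free), 1, prob = deg[free] + 1)]
      add_edge(i, j)
      deg[i] <- deg[i] + 1; deg[j] <- deg[j] + 1
      budget <- budget - 1
    }
    list(edges = data.frame(gene_a = nodes[edge_a], gene_b = nodes[edge_b],
                            stringsAsFactors = FALSE),
         hubs = hubs)
  })
}

#' Generate a complete synthetic input bundle
#'
#' Produces the seven pipeline inputs (compound table, fingerprints,
#' activity records, drug-target interaction library, disease gene
#' list, PPI edges, pathway annotation, docking scores) plus a
#' ground-truth sidecar recording every planted signal: the effective
#' compounds that must survive the screen, the planted PPI hubs (each
#' wired to known interactions from at least two effective compounds),
#' the planted enriched pathway, and the planted strong binders whose
#' docking score beats every competitor at their target by a fixed gap.
#'
#' Strong binders are planted among the interactions the diffusion
#' predictor actually produces on the generated bundle, so that - given
#' the planted score gap - the critical-selection stage must recover
#' them exactly.
#'
#' @param spec A [simulation_spec()].
#' @param dir Optional output directory; when given, all inputs are
#'   written as plain-text files plus `truth.json` and `spec.json`.
#' @return The bundle as a list: `compounds`, `fingerprints`,
#'   `activities`, `dti`, `disease_genes`, `ppi`, `pathways`, `dock`,
#'   `truth`, `spec`.  Written files are listed in attribute `files`
#'   when `dir` is given.
#' @export
gen_bundle <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  bundle <- with_seed(spec$seed, gen_bundle_impl(spec))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      compounds = file.path(dir, "compounds.tsv"),
      fingerprints = file.path(dir, "fingerprints.tsv"),
      activities = file.path(dir, "activities.tsv"),
      dti = file.path(dir, "dti_edges.tsv"),
      disease_genes = file.path(dir, "disease_genes.txt"),
      ppi = file.path(dir, "ppi_edges.tsv"),
      pathways = file.path(dir, "pathways.gmt"),
      dock = file.path(dir, "dock_scores.tsv"))
    write_tsv(bundle$compounds, files["compounds"])
    write_fingerprints(bundle$fingerprints, files["fingerprints"])
    write_tsv(bundle$activities, files["activities"])
    write_tsv(bundle$dti, files["dti"])
    write_gene_list(bundle$disease_genes, files["disease_genes"])
    write_tsv(bundle$ppi, files["ppi"])
    write_gmt(bundle$pathways, files["pathways"])
    write_tsv(bundle$dock, files["dock"])
    jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(bundle, "files") <- files
  }
  bundle
}

gen_bundle_impl <- function(spec) {
  ids <- sprintf("MOL%02d", seq_len(spec$n_compounds))
  cls <- c(rep("prototype", spec$n_prototype),
           rep("metabolite", spec$n_metabolite))
  # herb origins for prototypes; metabolites are unclassified
  origin <- rep("UNKNOWN", spec$n_compounds)
  origin[cls == "prototype"] <-
    sample(c("RA", "RG", "BOTH"), spec$n_prototype, replace = TRUE,
           prob = c(4, 8, 5))

  effective <- sort(sample(ids, spec$n_effective))
  non_eff <- setdiff(ids, effective)
  no_structure <- utils::head(non_eff, spec$n_no_structure)
  excluded <- utils::head(setdiff(non_eff, no_structure),
                          spec$n_excluded_class)

  # fold-change series: lognormal baseline capped strictly below the
  # screening threshold; effective compounds get 1-3 absorption spikes
  fc <- matrix(NA_real_, spec$n_compounds, 16,
               dimnames = list(ids, fc_columns()))
  for (i in seq_len(spec$n_compounds)) {
    base <- pmin(stats::rlnorm(16, 0, spec$fc_baseline_sdlog),
                 0.9 * spec$fc_threshold)
    miss <- stats::runif(16) < spec$fc_missing_rate
    if (all(miss)) miss[sample.int(16, 1)] <- FALSE
    base[miss] <- NA_real_
    fc[i, ] <- base
  }
  for (cid in effective) {
    k <- sample(1:3, 1)
    present <- which(!is.na(fc[cid, ]))
    periods <- sample(present, min(k, length(present)))
    spike <- pmax(stats::rlnorm(length(periods), spec$fc_spike_meanlog,
                                spec$fc_spike_sdlog),
                  2 * spec$fc_threshold)
    fc[cid, periods] <- spike
  }

  compounds <- data.frame(
    compound_id = ids,
    name = paste0("compound-", ids),
    structure = synth_smiles(spec$n_compounds),
    compound_class = cls,
    herb_origin = origin,
    class_tags = "",
    stringsAsFactors = FALSE)
  compounds$structure[ids %in% no_structure] <- ""
  compounds$class_tags[ids %in% excluded] <- "amino_acid"
  compounds <- cbind(compounds, as.data.frame(fc))
  compounds <- validate_compound_table(compounds, source = "synthetic")

  # target universe and drug-target interaction library; library drugs
  # hit disease-listed targets preferentially (druggable-bias), keeping
  # the disease-overlap portion of the network well covered
  targets <- sprintf("TG%03d", seq_len(spec$n_targets))
  libs <- sprintf("LIB%03d", seq_len(spec$n_library_drugs))
  hubs <- sort(sample(targets, spec$n_planted_hubs))
  disease_targets <- union(hubs, sample(setdiff(targets, hubs),
                                        spec$n_disease_targets -
                                          length(hubs)))
  target_weight <- ifelse(targets %in% disease_targets, 3, 1)
  dti <- do.call(rbind, lapply(libs, function(d) {
    data.frame(compound_id = d,
               target_gene = sample(targets, sample(3:6, 1),
                                    prob = target_weight),
               stringsAsFactors = FALSE)
  }))

  # fingerprints: library drugs random; effective compounds inherit a
  # donor drug's keys (noisy copy), giving the diffusion exploitable
  # substructure signal; other structured compounds are random
  dict <- sprintf("K%03d", seq_len(spec$fingerprint_dict_size))
  fp <- lapply(libs, function(d) sample(dict, spec$bits_per_compound))
  names(fp) <- libs
  donors <- stats::setNames(sample(libs, length(effective), replace = TRUE),
                            effective)
  structured <- compounds$compound_id[nzchar(compounds$structure)]
  for (cid in structured) {
    if (cid %in% effective) {
      keys <- fp[[donors[cid]]]
      keys <- keys[stats::runif(length(keys)) > spec$fingerprint_noise]
      extra <- sample(setdiff(dict, keys), 1)
      fp[[cid]] <- unique(c(keys, extra))
    } else {
      fp[[cid]] <- sample(dict, spec$bits_per_compound)
    }
  }

  # planted hubs: disease-listed targets wired (below) into the PPI
  # core and given known activities from three effective compounds each
  activities <- list()
  kinds <- c("Ki", "Kd", "IC50", "EC50")
  for (h in hubs) {
    for (cid in sample(effective, 3)) {
      activities[[length(activities) + 1]] <- data.frame(
        compound_id = cid, target_gene = h,
        measure_kind = sample(kinds, 1),
        value_uM = stats::runif(1, 0.05, 9),
        source = "synthetic", stringsAsFactors = FALSE)
    }
  }
  for (cid in sample(effective, 8)) {
    for (j in seq_len(sample(1:3, 1))) {
      activities[[length(activities) + 1]] <- data.frame(
        compound_id = cid, target_gene = sample(targets, 1),
        measure_kind = sample(kinds, 1),
        value_uM = stats::rlnorm(1, log(8), 1),
        source = "synthetic", stringsAsFactors = FALSE)
    }
  }
  activities <- do.call(rbind, activities)

  # disease gene list: the disease targets plus non-target decoys
  decoys <- sprintf("DZ%04d", seq_len(spec$n_disease_decoys))
  disease_genes <- sort(c(disease_targets, decoys))

  # PPI network over disease-listed targets with the hubs planted
  ppi_nodes <- union(hubs, sample(setdiff(disease_targets, hubs),
                                  spec$n_ppi_nodes - length(hubs)))
  ppi <- gen_ppi_with_hubs(sort(ppi_nodes), spec$n_ppi_edges, hubs,
                           boost = spec$hub_degree_boost,
                           seed = spec$seed + 101L)

  # pathway annotation: every target belongs to at least one random
  # pathway; the planted pathway collects the hubs plus a few extras
  sizes <- sample(spec$pathway_size_range[1]:spec$pathway_size_range[2],
                  spec$n_pathways - 1, replace = TRUE)
  pathways <- lapply(sizes, function(s) sample(targets, s))
  uncovered <- setdiff(targets, unlist(pathways))
  for (g in uncovered) {
    j <- sample.int(length(pathways), 1)
    pathways[[j]] <- unique(c(pathways[[j]], g))
  }
  planted_name <- "PLANTED_FIBROSIS_PATHWAY"
  planted_set <- unique(c(hubs,
                          sample(setdiff(ppi_nodes, hubs),
                                 spec$enriched_pathway_extras)))
  pathways <- c(list(planted_set), pathways)
  names(pathways) <- c(planted_name,
                       sprintf("PATHWAY_%02d", seq_along(sizes)))
  pathways <- lapply(pathways, function(g) {
    g <- sort(unique(g)); attr(g, "description") <- "synthetic"; g
  })

  # docking scores: cover every (screened compound, PPI target) pair the
  # predictor produces, then plant one strong binder per hub target
  screened <- screen_compounds(compounds, spec$fc_threshold,
                               exclusion_tags = "amino_acid")
  known <- filter_known_ctis(activities, 10)
  known <- known[known$compound_id %in% screened$retained, , drop = FALSE]
  sdt <- suppressWarnings(
    build_sdt_network(rbind(dti, known[, c("compound_id", "target_gene")]),
                      fp))
  query <- intersect(screened$retained, sdt$drugs)
  pred <- predict_targets(sdt, query, top_k = 20)
  merged <- merge_cti(known, pred$predictions)
  cand <- merged[merged$target_gene %in% ppi_nodes, , drop = FALSE]
  dock <- unique(cand[, c("compound_id", "target_gene")])
  dock$gscore <- round(stats::rnorm(nrow(dock), spec$gscore_mean,
                                    spec$gscore_sd), 3)
  strong <- list()
  pred_cand <- merged[merged$origin == "predicted" &
                        merged$target_gene %in% hubs, , drop = FALSE]
  for (h in hubs) {
    rows <- which(dock$target_gene == h &
                    paste(dock$compound_id, dock$target_gene) %in%
                      paste(pred_cand$compound_id, pred_cand$target_gene))
    if (length(rows) == 0) next
    fc_max <- compounds$fc_max[match(dock$compound_id[rows],
                                     compounds$compound_id)]
    pick <- rows[order(-fc_max, dock$compound_id[rows])[1]]
    floor_score <- min(dock$gscore[dock$target_gene == h])
    dock$gscore[pick] <- round(floor_score - spec$gscore_planted_gap, 3)
    strong[[length(strong) + 1]] <- data.frame(
      compound_id = dock$compound_id[pick], target_gene = h,
      gscore = dock$gscore[pick], stringsAsFactors = FALSE)
  }
  strong <- if (length(strong) > 0) do.call(rbind, strong) else
    data.frame(compound_id = character(0), target_gene = character(0),
               gscore = numeric(0), stringsAsFactors = FALSE)

  truth <- list(
    effective_compounds = effective,
    removed_no_structure = no_structure,
    removed_excluded_class = excluded,
    fingerprint_donors = as.list(donors),
    planted_hubs = hubs,
    enriched_pathway = planted_name,
    strong_binders = strong)

  list(compounds = compounds, fingerprints = fp, activities = activities,
       dti = dti, disease_genes = disease_genes, ppi = ppi$edges,
       pathways = pathways, dock = dock, truth = truth, spec = spec)
}
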