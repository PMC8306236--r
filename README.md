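# herbnet

Network pharmacology for multi-component herbal medicines profiled by
in-vivo metabolomics.

Classical herbal formulas act through dozens of constituents — both the
prototype compounds present in the herbs and the metabolites formed
after administration — each touching many protein targets. `herbnet`
implements a reproducible pipeline for dissecting such a formula's
mechanism of action against a disease (the motivating application is a
two-herb decoction of *Radix Astragali* and *Radix Glycyrrhizae* used
against liver fibrosis):

1. **Compound screening.** Constituents carry a 16-period plasma
   fold-change (Fc) series from a pharmacokinetic metabolomics study.
   A compound is kept only if it has a structure, is not on a curated
   exclusion list (amino acids, short aliphatic chains, trivially simple
   molecules), and its maximum fold change `FC_MAX = max_t Fc_t`
   reaches 2 — i.e. its plasma level actually responds to dosing.
2. **Target prediction.** Known compound–target interactions (CTIs;
   Ki/Kd/IC50/EC50 ≤ 10 µM) are merged with predictions from two-phase
   resource diffusion on a substructure–drug–target network: a
   tripartite graph whose drug layer links to targets (known
   interactions) and to molecular substructure keys (fingerprints).
   Resource placed on a query compound spreads to its neighbours and
   back, and after `k` rounds the mass on the target layer ranks
   candidate targets (top 20 kept per compound).
3. **Disease network.** Targets are intersected with a disease gene
   list and the compound–disease-target bipartite network is built,
   with compounds labelled by herb origin (RAC/RGC/RAGC/MC).
4. **Hub genes.** On the protein–protein interaction (PPI) network of
   those targets, four centralities are computed — Edge Percolated
   Component (EPC, Monte-Carlo edge percolation), EcCentricity (EC),
   Closeness (Clo), Radiality (Rad), with cytoHubba's conventions.
   Each measure's values are dense-ranked (ties share a rank, the next
   distinct value increments the rank by one) and a target scores
   `S_i = Σ_m 1[R_m,i < median_j R_m,j]` over the four measures.
   Hubs are targets with `S_i > 1` interacting with more than one
   compound (plus optional curated additions).
5. **Pathway enrichment.** Hub genes are tested per pathway with the
   exact hypergeometric upper tail `P(X ≥ k)` and Benjamini–Hochberg
   FDR < 0.05, followed by declarative curation (glob patterns, e.g.
   `*cancer*`) of pathways unrelated to the disease.
6. **Critical interactions.** CTIs to the enriched hub targets are
   filtered by in-vivo concentration (metabolites need
   `FC_MAX > 10` for PPARG/PTGS2, `> 5` for PPARD/SERPINE1 by default),
   then per target the known CTI with the largest FC_MAX and the
   predicted CTI with the lowest docking score / highest FC_MAX
   (Pareto resolution, configurable) are selected and assembled into
   the critical bipartite network.

A first-class synthetic-data generator (`simulation_spec()`,
`gen_bundle()`) produces all seven pipeline inputs with planted ground
truth — effective compounds, PPI hubs, an enriched pathway, strong
binders — so the whole chain is testable offline.

## Worked example

The critical-interaction stage, run on the published worked example —
seven predicted CTIs with their Glide docking scores plus three known
CTIs:

```r
library(herbnet)

dock <- data.frame(
  compound_id = c("MOL39","MOL67","MOL18","MOL43","MOL43","MOL43","MOL10"),
  target_gene = c("CDK1","MMP9","PPARD","PPARG","PTGS2","SERPINE1","PTGS2"),
  gscore      = c(-6.125,-6.906,-7.786,-7.534,-8.253,-6.667,-8.29))

split <- gscore_median_split(dock)
attr(split, "median")
#> [1] -7.534                      # the MOL43-PPARG score
min(split$gscore)
#> [1] -8.29                       # MOL10-PTGS2, the strongest binding

crit <- rbind(
  cbind(dock, origin = "predicted"),
  data.frame(compound_id = c("MOL14","MOL52","MOL17"),
             target_gene = c("TP53","TP53","HIF1A"),
             gscore = NA, origin = "known"))
# compounds: a compound table carrying each compound's FC_MAX
g <- build_critical_network(crit, compounds)
igraph::vcount(g); igraph::ecount(g)
#> [1] 16                          # 8 compounds + 8 targets
#> [1] 10                          # 7 predicted + 3 known edges
igraph::degree(g, "MOL43")
#> MOL43
#>     3                           # PTGS2, PPARG and SERPINE1
```

End to end on synthetic data:

```r
bundle <- gen_bundle(simulation_spec(seed = 7), dir = "bundle/")
res <- run_pipeline_stages(bundle, pipeline_config(seed = 7,
                           exclusion_tags = "amino_acid"))
setequal(res$screen$retained, bundle$truth$effective_compounds)
#> [1] TRUE
all(bundle$truth$planted_hubs %in% res$hubs$node[res$hubs$hub])
#> [1] TRUE
res$enrichment$pathway[1]
#> [1] "PLANTED_FIBROSIS_PATHWAY"
```

A thin command-line wrapper lives at `inst/cli/herbnet.R`
(`Rscript herbnet.R simulate|run --seed N --out DIR`).

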