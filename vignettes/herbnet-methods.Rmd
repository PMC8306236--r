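---
title: "Methods: screening, diffusion prediction, hub scoring and critical-interaction selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, diffusion prediction, hub scoring and critical-interaction selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

`herbnet` turns a published systems-pharmacology workflow for
multi-component herbal medicines into a tested, reusable pipeline. This
vignette is the package's own account of the underlying models, the
tunable parameters, the numerical choices made where the procedure was
genuinely open, and what the synthetic benchmark does and does not
show.

## The pipeline and its assumptions

The object of study is a herbal formula whose constituents — prototype
compounds and their in-vivo metabolites — were profiled by
pharmacokinetic metabolomics: each compound carries a series of fold
changes (Fc) of its plasma abundance at 16 post-dose time periods
relative to baseline. The pipeline's premise is that only constituents
that actually reach the circulation at responsive levels can act, and
that their protein targets, taken together as a network against a
disease gene set, expose the formula's mechanism of action.

### Compound screening

`screen_compounds()` removes a compound when (i) it has no structure,
(ii) it carries a curated exclusion tag, or (iii) **all** observed Fc
values are strictly below the threshold (default 2) — equivalently,
when `FC_MAX < 2`. The all-quantified reading of rule (iii) is the only
one consistent with its rationale (compounds whose concentration never
responds to dosing are not considered effective): the existential
reading would delete almost everything. A value exactly at the
threshold keeps the compound, since the rule deletes values *less
than* the threshold; the boundary behaviour is asserted in the tests
rather than assumed elsewhere. Missing periods are stored as absent
(`NA`), never as zero — a zero would count as evidence of
non-absorption, an absent measurement is no evidence at all — and
`FC_MAX` is the maximum over present values. Removal reasons are
reported with the fixed precedence *no structure > excluded class >
low fold change*, mirroring the order in which the rules are stated,
so reports are reproducible when several rules apply.

The exclusion classes (amino acids and derivatives, short aliphatic
chains, trivially simple molecules) are implemented as a tag
blocklist, not structure perception: the original screening applied
them by curation, and inferring chemical classes from SMILES would
substitute our judgment for the curator's.

### Target prediction by resource diffusion

Known interactions are activity records with Ki, Kd, IC50 or EC50
≤ 10 µM (`filter_known_ctis()`; the boundary value is kept). For
prediction, `build_sdt_network()` assembles a tripartite graph: drug
nodes link to target nodes (known drug–target interactions, typically
a global interaction library) and to substructure-key nodes
(fingerprint membership). There are no edges inside the target or
substructure layers.

`predict_targets()` performs two-phase network-based inference. Let
`A` be the adjacency matrix and `T` the column-stochastic transition
`T[i,j] = A[i,j] w_i / Σ_l A[l,j] w_l` with `w_i = deg(i)^α`. One unit
of resource starts on the query drug; one *round* spreads it to the
drug's neighbours and back (`T` applied twice), and after `k` rounds a
final half-step moves it onto the target layer, whose entries are the
prediction scores — `T^(2k+1) e_d` restricted to targets. Defaults are
`k = 2` rounds and `α = 0` (equal splitting, the classical unweighted
rule); the allocation exponent is exposed because published variants
of substructure-augmented inference tune such weights, but their exact
defaults are not restated here — when known they can be set in the
configuration. Two properties anchor the implementation: the
transition conserves total resource (tested to 1e-9), and on networks
of ≤ 20 nodes the scores equal an independently coded dense
matrix-power computation.

Per compound, the top `top_k = 20` *novel* targets are returned;
targets already known for that compound are excluded from the ranked
list but reported alongside it, and `merge_cti()` gives the known
origin priority when a pair occurs in both channels. All ranked lists
break ties by score, then lexicographic gene symbol, so results are
invariant to input row order.

### The bipartite disease network

`map_disease_genes()` is an exact set intersection on normalized
(uppercase) symbols; an empty intersection is an error ("empty
intersection") because every downstream stage would be meaningless.
`build_clft_network()` keeps only edges into the disease overlap,
drops compounds left edgeless (the published figures render only
interacting nodes), and labels compounds RAC/RGC/RAGC (herb origin of
prototypes) or MC (metabolites). The full interaction table is still
written out, so the network filter loses no data.

### Hub scoring by median-rank aggregation

The four node-ranking measures are named but not defined in the
original workflow; definitions follow the cytoHubba tool it used:

* `Clo(v) = Σ_w 1/dist(v, w)` (unreachable pairs contribute 0);
* `EC(v) = 1 / ecc(v)` with the eccentricity taken within `v`'s
  component;
* `Rad(v) = Σ_{w∈C_v} (Δ_C + 1 − dist(v, w)) / (n_C − 1)` with `Δ_C`
  the component diameter;
* `EPC(v)`: over seeded Monte-Carlo replicates in which each edge is
  kept independently with probability `p = 0.5` (1000 replicates by
  default), the mean size of the component containing `v`.

Distance measures are computed within components because the PPI input
need not be connected; isolated vertices receive the minimum of every
measure and hence rank last. EPC is bit-reproducible for a fixed seed,
and on small graphs the Monte-Carlo mean is tested against exhaustive
enumeration of all edge subsets (within three standard errors computed
from the exact variance).

Each measure is **dense-ranked** (tied scores share a rank; the next
distinct score's rank increases by exactly one — so ranks depend only
on the set of distinct values) and a target's score is

> S_i = Σ_m 1[ R_m,i < median_j R_m,j ],  m ∈ {EPC, EC, Clo, Rad},

a strict comparison against the median rank, giving S_i ∈ {0, …, 4}.
Hubs are targets with `S_i > 1` that interact with more than one
compound in the global network. Whether "interacting compounds" counts
known and predicted interactions together is not stated in the source;
the package counts both by default and exposes per-origin counts.
Curated additions can be forced in (`manual_hubs`) and are flagged as
such in the output.

### Enrichment

The original workflow delegated pathway analysis to a remote service;
for offline reproducibility the package implements the standard
over-representation test: the exact hypergeometric upper tail
`P(X ≥ k)` for `k` hub genes among `K` pathway members, `n` hub genes
and `N` background genes, with Benjamini–Hochberg control at
FDR < 0.05. The background defaults to the union of the annotation's
genes and is configurable; no default pretends to be the remote
service's universe. Curation of the significant list (removal of, say,
cancer pathways when the disease is fibrosis) is declarative — glob
patterns plus an overriding keep list — because the published deletion
was expert judgment; curation flips only the `retained` flag, never
the statistics.

### Critical-interaction selection

Interactions with the enriched hub targets pass a concentration
filter: metabolites binding a target with a configured threshold need
`FC_MAX` strictly greater than it (defaults: 10 for PPARG and PTGS2, 5
for PPARD and SERPINE1 — the four high-degree targets for which
thresholds were stated; all other targets, and all prototype
compounds, pass unchanged, flagged in the report).

Selection then runs two channels per target: the known interaction
whose compound has the largest `FC_MAX`, and the predicted interaction
with "lower docking score and greater fold change". That joint
criterion is under-specified when the two orders conflict. The default
policy restricts to the Pareto front of (minimize score, maximize fold
change) and then prefers the lower score, then the higher fold change,
then the lexicographically smaller compound id — at most one winner
per channel. Three alternatives are configurable: score-only,
fold-change-only, and `pareto_all`, which keeps every non-dominated
candidate; `pareto_all` is the only reading under which one target can
retain two predicted interactions whose orders conflict, which is
precisely the pattern shown by the published critical network (two
predicted binders of PTGS2: one with the best score, one with the far
higher fold change). The flagship compound of the worked example is
insensitive to the choice, being best in both orders among its
candidates.

Docking itself is out of scope: scores are consumed as input data and
bit-copied to outputs. On the question of direction, the workflow's
text contains both conventions ("greater than the median" indicates
strong binding vs "the lower the score the stronger"); the package
defaults to *below the median = strong*, the convention consistent
with the reported results and with docking practice, and exposes the
alternative. Records equal to the median are weak under either rule.
`cross_dock_consistency()` reports, per selected target, whether the
selected compound attains the best score among all compounds docked to
that target.

## The synthetic benchmark

`gen_bundle()` generates all seven inputs with planted, recorded
truth. The study-scale defaults are: 68 compounds (17 prototypes, 51
metabolites) of which 40 are planted effective; a 300-gene target
universe with a 150-drug interaction library (3–6 targets per drug,
biased 3:1 toward disease-listed targets, reflecting the druggability
bias of curated interaction databases); 95 disease-overlap targets
inside a 1192-gene disease list; a 48-node, 71-edge PPI network with 3
planted hubs; 15 pathway annotations; and normally distributed docking
scores (mean −5, sd 1).

Fold-change series are lognormal baselines capped strictly below the
screening threshold, with 1–3 multiplicative absorption spikes
(lognormal, floored at twice the threshold) for effective compounds —
the screen consults only the 16-value series, so no pharmacokinetic
model is needed, and the cap/floor construction makes screen recovery
exact by design. Fingerprints of effective compounds are noisy copies
of a library donor drug's key set, giving the diffusion exploitable
substructure signal without any chemistry engine. Planted hubs receive
8 extra edges each (within the exact 71-edge budget) and known
sub-10-µM activities from three effective compounds, so both halves of
the hub rule are satisfiable. The planted enriched pathway is the hub
module itself — the strongest detectable signal at these set sizes.
Planted strong binders are chosen among the predicted candidates the
(deterministic) predictor produces on the bundle, and their docking
score is set to the per-target minimum minus a fixed gap (1.5), so
their selection is a property of the construction rather than of
chance.

What passing recovery shows — and what it does not: the screen
recovers planted effective compounds exactly on every seed; planted
hubs and the planted pathway are recovered on ≥ 95 % of 100 seeds
(occasionally a hub's centrality falls below the median-rank rule and,
with it, no pathway reaches significance — the pipeline then stops
honestly at the selection stage); planted strong binders are selected
exactly whenever the pipeline completes. None of this validates the
biology of any real formula: the generator emulates the *shapes* of
the inputs (series, graphs, score tables), not mass-spectrometry
noise, real chemistry, or docking physics.

## Numerical and reproducibility choices

* Every stochastic step (EPC percolation, bundle generation) takes an
  explicit integer seed; EPC restores the caller's RNG state. Stage
  outputs embed the configuration hash and seed in header comments,
  and reruns are byte-identical.
* The recovery loops run EPC at 200 replicates instead of the default
  1000: EPC enters hub scoring only through dense ranks, which are
  stable at that precision on 48-node graphs; single-run analyses keep
  the 1000-replicate default.
* Degenerate inputs fail loudly at the owning stage with the stage
  name in the message: an all-absent Fc series, an empty known-CTI
  list, an empty disease intersection, an empty docking table.
* Ties are never left to hash or input order: ranked lists and
  selections break ties by the stated keys ending in a lexicographic
  identifier.

## Known limitations

* The diffusion predictor is a generic two-phase substructure-
  augmented inference; it does not reproduce any specific published
  score normalization, and its exponents default to the unweighted
  rule.
* The enrichment background is whatever annotation is supplied;
  results are not comparable across annotation versions.
* Herb-origin classification consumes literature/concentration
  evidence flags; it does not do literature search.
* The concentration filter applies no rule to prototype compounds,
  the most conservative reading of a passage that states thresholds
  only for metabolites; prototypes are flagged in the report so users
  can apply their own rule.
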