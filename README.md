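# mgtnet

Tissue-specific miRNA–gene–TF regulatory networks and prognostic gene
signatures, in R.

## What problem this solves

Curated interaction databases say which transcription factors (TFs)
regulate which genes and miRNAs, which miRNAs silence which targets,
and which host genes are co-transcribed with their intronic miRNAs —
but not whether those interactions operate in a particular tissue.
Pure co-expression analysis, on the other hand, is riddled with false
positives (a TF driving a miRNA up and a gene down fakes a direct
miRNA–gene interaction).  `mgtnet` fuses the two: candidate edges come
from user-supplied interaction tables (TSV), and paired gene/miRNA
expression matrices over matched samples decide which candidates are
active and how strong they are.  It is aimed at computational
biologists building regulatory networks from RNA-seq or microarray
cohorts, and at anyone who wants small prognostic gene signatures with
honest multi-cohort gating.

## The method in brief

1. **Assembly** — typed directed edges (`tf_gene`, `tf_mirna`,
   `mirna_gene`, `host_mirna`) restricted to measured features;
   self-loops, duplicates and isolated nodes removed.
2. **Correlation screen** — per-edge Spearman ρ; `mirna_gene` edges
   must have ρ < 0, `host_mirna` edges ρ > 0; within each (type, sign
   of ρ) group only edges in the top `spearman_keep_percent` of |ρ|
   (default 10%) survive.
3. **Ridge scoring** — each node *B* with regulators *A₁…Aₙ* is fitted
   as *y = c₀ + c₁x₁ + … + cₙxₙ + ε* by ridge regression on z-scored
   data.  The node's **incoming score** is the fit's R²; each edge's
   **interaction score** is |βᵢ|, the standardized beta of its source.
4. **Significance filter** — nodes with incoming R² < 0.3 lose their
   incoming edges; the bottom 10% of interaction scores is cut;
   isolated nodes are dropped.  Every remaining node significantly
   regulates and/or is significantly regulated.
5. **Topology** — degrees, weak/strong components, centralities,
   GraphML + TSV export, and degree significance calibrated against
   directed Erdős–Rényi *G(n, M)* random graphs.
6. **Signatures** — exhaustive search over k-gene combinations of the
   top-n genes (n bounded by a `k·C(n,k)` cost budget), linear SVM
   with balanced class weights, C selected by stratified 5-fold CV,
   gated at AUC/sensitivity/specificity ≥ 0.65 on training and
   filtration cohorts, validated on an independent cohort, with
   repeated-CV and cross-platform filtration modes.

A planted-structure generator (`generate_planted_network()`)
simulates exactly the linear-Gaussian model the scorer assumes, with
signed typed edges plus decoys, so the whole pipeline is testable
against known ground truth without any external data.

## Worked example

```r
library(mgtnet)

# a planted system: 55 nodes, 90 true edges, 45 decoys, 200 samples
sys <- generate_planted_network(seed = 1)
sys
#> PlantedSystem: 55 nodes, 90 planted + 45 decoy edges, 200 samples (seed 1)

# full pipeline; retention matched to the planted candidate density
cfg <- net_config(spearman_keep_percent = 80)
net <- build_network(sys$tables, sys$genes, sys$mirnas, cfg)
net
#> RegulatoryNetwork: 55 node(s) (11 TF, 29 other gene, 15 miRNA), 91 edge(s)
#>   edges by type: host_mirna=2, mirna_gene=13, tf_gene=49, tf_mirna=27

recovery_stats(sys, net)[c("recall", "precision", "decoys_retained")]
#> recall 0.989  precision 0.978  decoys retained 2

topology_report(net)
#> TopologyReport: 55 nodes (11 TF / 29 gene / 15 miRNA), 91 edges
#>   nodes with incoming edges: 83.6%; with outgoing: 36.4%
#>   weak components: 1 (largest 55); nontrivial SCCs: 1
```

Of the 90 planted interactions, 89 survive the screens and score-based
filters (recall 0.989) and only 2 of the 45 decoys sneak through
(precision 0.978).  Degree significance against the matching random
graph null:

```r
er_degree_significance(n = 336, M = 504, d = 8, reps = 1e5, seed = 1)
#> $estimate 0.00841   $se 0.00029
```

i.e. a directed G(336, 504) graph contains a node of in-degree > 8
with probability ≈ 0.008, so hubs of that degree in a real network of
this size are significant at the 1% level.

For real data, start from `read_expression()` / `read_interactions()`
and the preprocessing chain `collapse_duplicates() |> to_tpm() |>
log2_and_filter()` followed by `align_samples()`.  A thin command-line
wrapper with `simulate`, `build-network`, `analyze-topology` and
`search-signatures` subcommands lives in `inst/cli/mgtnet.R`.

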