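# nlrmacro

Desk-scale tools for surveying the macroevolution of plant **NLR**
(nucleotide-binding, leucine-rich-repeat) intracellular immune receptors.
NLR surveys across divergent plant lineages chain together a characteristic
set of computational steps — domain-architecture annotation, sequence
clustering, iterative phylogenetic cleaning, structure-similarity network
clustering, N-terminal motif profiling, and cross-species expression
comparison — each of which is usually delegated to a separate external tool.
`nlrmacro` implements that chain as one tested R package, with a seeded
synthetic-data generator that produces inputs with known ground truth for
every stage, so each procedure can be validated end to end.

## What the package computes

* **Architecture classification** (`classify_nlr`, `nlr_inventory`). From a
  per-protein domain-hit table: proteins with a full NB-ARC domain are NLRs;
  a bare P-loop marks a degenerate NLR; RPW8, MLKL, TIR+hydrolase (TX) and
  CC+hydrolase (CC-X) patterns mark NLR-associated proteins. Subtypes (TIR,
  CC, CC_R, CC_CblN, Hyd, Pkn, NL) come from the highest-scoring canonical
  N-terminal domain preceding the NB-ARC; non-canonical fusions are
  inventoried as integrated domains (NLR-IDs) with an N/C terminus flag.
* **Sequence clustering** (`global_align`, `greedy_cluster`, `major_groups`).
  Greedy centroid clustering at 50 % identity and 50 % bidirectional
  coverage under BLOSUM62 global alignment (gap open 11, extend 1), with a
  "major group" filter (≥ 30 loci across ≥ 3 species).
* **Tree cleaning** (`filter_columns`, `nj_tree`, `flag_long_branches`,
  `trim_long_branches`, `iterative_clean`). The iterative homolog-cleaning
  loop: filter alignment columns below 10 % occupancy, build a tree, remove
  every branch that is ≥ 1.0 substitutions/site (absolute rule) or ≥ 0.5
  subs/site *and* ≥ 10× its sister branch (relative rule), repeat up to 13
  rounds or until a fixed point, then one final terminal-only pass. Aligner
  and tree builder are pluggable; the built-ins are pass-through alignment
  and neighbor joining on p-distances.
* **Structure networks** (`build_graph`, `louvain`, `modularity_q`,
  `filter_communities`, `crosstab`). Thresholds all-vs-all normalized
  TM-scores at τ = 0.5, detects communities by seeded Louvain modularity
  optimisation (weighted Newman–Girvan objective
  Q = Σ_c [w_c/m − (K_c/2m)²]), and cross-tabulates structure communities
  against sequence groups.
* **Motif profiling** (`build_profile`, `score_sequence`,
  `scan_and_summarize`, `consensus_counts`). Builds a profile HMM from a
  curated N-terminal motif alignment (MAEPL/MADA style): match states at
  ≥ 50 % column occupancy, pseudocount-smoothed log-odds emissions in bits,
  transitions from the observed gap structure. Scores proteomes by Viterbi
  or forward dynamic programming, glocal in the profile and local in the
  sequence.
* **Cross-species concordance** (`filter_degs`, `map_orthologs`,
  `concordance`, `sector_enrichment`, `deg_overlap`). Filters DEG tables at
  |log2FC| ≥ 2 and adjusted p ≤ 10⁻³, collapses genes to orthogroups by
  unanimous direction, counts the up/up–down/down–up/down–down/up quadrants
  and the concordance fraction, and runs hypergeometric (Fisher) enrichment
  with Benjamini–Hochberg correction per sector.
* **Synthetic data** (`sim_config`, `gen_proteome`, `plant_motif`,
  `gen_tree_with_outliers`, `gen_tm_matrix`, `gen_deg_tables`,
  `simulate_dataset`). Seeded generators for every input above, each with
  complete truth labels.

## Worked example

```r
library(nlrmacro)
res <- run_pipeline("pipe_demo", seed = 1)

res$treeclean[c("planted_recall", "baseline_removed")]
#> $planted_recall
#> [1] 1
#> $baseline_removed
#> [1] 0

res$structnet[c("modularity", "n_communities", "ari_vs_truth")]
#> $modularity
#> [1] 0.7499966
#> $n_communities
#> [1] 4
#> $ari_vs_truth
#> [1] 1

round(res$xspecies$concordance, 3)
#> [1] 0.64
```

The pipeline simulated one dataset (600 proteins in 3 species, a 30-tip
tree with 6 planted long-branch outliers, a 100-model similarity matrix
with 4 planted communities, and 600 two-species orthogroups with a planted
concordance of 0.62), then ran all six stages. Cleaning removed all 6
planted outliers and no baseline tip; Louvain recovered the 4 planted
communities exactly (adjusted Rand index 1) at modularity 0.75; the
realised cross-species concordance of the seed-1 dataset is 0.64, which the
quadrant analysis recovers exactly.

A thin command-line wrapper ships in `inst/cli/nlrmacro.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","nlrmacro.R",package="nlrmacro"))')" \
    pipeline --out pipe_demo --seed 1
```

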