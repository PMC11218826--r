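---
title: "Methods: desk-scale NLR macroevolution analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale NLR macroevolution analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlrmacro)
```

`nlrmacro` reimplements, at desk scale, the computational chain used in
macroevolutionary surveys of plant NLR immune receptors. This vignette is
the package's own account of each procedure: the model, its assumptions,
the tunable parameters, the numerical choices, and what the synthetic
benchmark does and does not demonstrate.

## Scope and division of labour

Large NLR surveys depend on heavy external machinery — genome-scale domain
annotation, structure prediction, TM-score computation, maximum-likelihood
tree inference, orthogroup inference, and RNA-seq quantification. The
package deliberately consumes the *outputs* of those steps as plain-text
inputs (domain-hit tables, pairwise similarity edge lists, orthogroup maps,
DEG tables) and owns everything downstream: classification logic, cluster
and community detection, the cleaning loop, motif scoring, and concordance
statistics. Alignment and tree building inside the cleaning loop are
pluggable callables, so maximum-likelihood inference can replace the
built-in neighbor joining without changing the loop.

## Architecture classification

A protein is an **NLR** exactly when it carries a full NB-ARC hit; a P-loop
hit without NB-ARC marks a **degenerate NLR**; proteins with neither are
**NLR-associated** when they match RPW8, MLKL, TIR + hydrolase (TX) or
CC + hydrolase (CC-X), and **none** otherwise. The subtype of an NLR is the
highest-scoring canonical N-terminal domain lying entirely N-terminal of
the anchor (`hit.end < anchor.start`, a strict ordering with no ambiguity);
score ties go to the anchor-proximal hit, which also resolves tandem CC–CC
architectures. When no such domain exists but an LRR follows the anchor,
the protein is an undefined/minimal **NL** receptor; otherwise `other`.
Overlapping hits are resolved before classification — higher score, then
longer hit, then N-terminal-most — a deterministic, score-respecting rule.
Coordinates are 1-based inclusive throughout. Non-canonical (`OTHER:<name>`)
hits become integrated domains with an N/C flag relative to the anchor.

Two classification choices were genuinely open. First, when both CC and
RPW8 precede one NB-ARC, the higher-scoring hit wins; this is a repository
decision, since published annotation tools do not document their
precedence. Second, MLKL is treated as part of the controlled domain
vocabulary rather than as an `OTHER:` label, because MLKL defines an
NLR-associated class and must not be inventoried as an integrated decoy
domain.

## Sequence clustering

`greedy_cluster` mirrors the 50 % identity / 50 % coverage sequence
grouping step with a transparent greedy centroid algorithm: sequences are
processed longest-first (lexicographic tie-break), each joining the first
centroid it matches or founding a new cluster. Pairwise statistics come
from optimal global alignment under BLOSUM62 with affine gaps (open 11,
extend 1; a gap of length L costs 11 + L). Identity is counted over
columns holding a residue in both sequences — the common "identity over
aligned columns" convention — and coverage must hold for **both**
sequences by default (the strictest common mode; a single-sided mode is
available), since the tools behind the published thresholds do not state
their coverage mode. The "major group" filter keeps clusters with at least
30 members spanning at least 3 species, both boundaries inclusive.

## Iterative tree cleaning

The cleaning loop runs align → occupancy filter → tree → trim for up to 13
rounds (the published round count) or until a round removes nothing.
Columns survive when their non-gap fraction is at least 0.10, boundary
inclusive. Branch removal applies two rules in a **single pass over the
input tree**: absolute (length ≥ 1.0 substitutions/site) and relative
(length ≥ 0.5 and ≥ 10× the sister branch). Flags are not re-evaluated
after individual removals within a pass — cascading effects are handled by
the iterative loop — which keeps each pass order-independent and matches a
rounds-based procedure. The final extra pass restricts both rules to
terminal branches, following the published final-pass restriction; during
the rounds the rules also apply to internal branches (configurable), and a
flagged internal branch splits the tree with only the larger tip set
retained (ties keep the side with the lexicographically smallest tip).

The "sister" of a branch is the stem of its sibling subtree at the parent
node; at polytomies the comparison uses the **longest** sister, a
conservative reading that removes only unambiguous outliers. Trees are
treated as unrooted: a degree-2 root is merged away before evaluation, so
rooted and unrooted encodings of the same tree trim identically.

The built-in tree builder is neighbor joining (via `ape`) on p-distances
computed over columns ungapped in both sequences, with negative estimated
branch lengths clamped to zero; pairs with no comparable columns get
distance 1. This is a dependency-free desk-scale substitute — model-based
maximum-likelihood inference remains the pluggable production choice.

## Structure-similarity networks

Pairwise normalized TM-scores in [0, 1] are thresholded at τ = 0.5
(boundary kept — a score of exactly 0.5 is significant structural
similarity); nodes appearing only in sub-threshold pairs remain as
isolates. Community detection is Louvain modularity optimisation on the
**weighted** graph: the underlying survey ran Louvain through igraph,
whose implementation accepts weights, so weighted is the default and an
unweighted mode is a flag. The objective is classic weighted
Newman–Girvan modularity at resolution 1.0.

The implementation is the standard two-phase algorithm (local moves to a
fixed point, then aggregation, repeated), with two robustness additions:
a node-level refinement pass on the original graph after aggregation, so
single nodes can still leave or split out of their community, and seeded
random-restart node orders (first restart sorted, subsequent restarts
shuffled at every level; best-Q partition kept). Both additions only ever
increase Q, and the result is deterministic for a fixed seed. Community
counting follows the published convention: communities need ≥ 2 members to
be tallied, and ≥ 20 members to be "major" (the published major clusters'
observed minimum of 24 is an observation, not the filter). The
sequence-group × structure-community cross-tab counts shared members over
ids present in both assignments and reports one-sided ids separately.

## Motif profiling

The profile HMM follows the classic architecture: match states for
alignment columns with ≥ 50 % occupancy (the standard heuristic; the
published pipeline delegates this to hmmbuild's internal rule), delete
states, and insert states between consecutive match columns emitting at
background. Match emissions are pseudocount-smoothed column frequencies,
`(counts + pc·bg) / (n + pc)`, converted to log-odds bits against the
background; transitions are estimated from the observed gap structure with
Laplace (+1) smoothing. The background is uniform by default (simplest
null, used throughout the tests), with a Robinson–Robinson table available.

Scoring is glocal: the whole profile aligns against any substring of the
target, flanking residues free — the right contract for short N-terminal
motifs sitting on much longer receptor sequences. Viterbi reports the best
single alignment (bit score and 1-based start); forward reports the
log-sum over all alignments and is never below Viterbi. Bit scores are raw
log-odds with no E-value calibration, matching the published use of raw
score distributions; the HMMER2-era calibration step mentioned alongside
the original profiling has no modern equivalent and is deliberately
omitted. Residues outside the 20-letter alphabet score as background and
are counted per hit.

## Cross-species concordance

DEG directions use the strict published cutoff, |log2FC| ≥ 2 and adjusted
p ≤ 10⁻³, boundary inclusive (the figure-legend "< 10⁻³" form is available
as a strict mode). Genes collapse to orthogroups by unanimous member
direction; orthogroups with internally conflicting directions are excluded
as "mixed" and reported, because the published counts are gene-level per
species and do not state a many-to-many resolution (majority-vote and
gene-pair-level modes are provided; the level used is recorded in the
output). Quadrant counts, mixed orthogroups and unmapped genes jointly
account for every shared orthogroup. Enrichment uses the hypergeometric
upper tail (one-sided Fisher) with Benjamini–Hochberg correction applied
within each sector across terms, significant at FDR ≤ 0.05.

## The synthetic generator

The generator's defaults are the benchmark conditions used throughout the
tests, chosen once:

* **Proteome**: 3 species × 200 proteins; an architecture mix dominated by
  CC- and TIR-type NLRs with smaller fractions of CC_R, CC_CblN, Hyd, Pkn
  and NL receptors plus degenerate, associated and background proteins;
  10 % of NLRs carry an integrated domain. Random sequence regions are
  uniform over the 20 canonical residues (simplest null; configurable).
  Domain coordinates are jittered but always non-overlapping and ordered.
* **Motif**: a synthetic MAEPL-style 17-mer consensus
  (`MAEPLVAKVGELAKRAG`) planted at position 1 with a 10 % per-position
  substitution rate.
* **Tree**: 30 tips, random topology by successive random tip attachment
  starting from a three-tip star (so every internal node has degree three
  and no arbitrary root exists); baseline branch lengths exponential with
  mean 0.1, **truncated below 0.5 substitutions/site**; 20 % of tips
  planted as outliers, half by the absolute rule (length ≥ 1.0), half by
  the relative rule (length in [0.55, 0.95) with every sister forced to
  1/20 of it), no two outliers sharing a parent. The truncation is a
  ground-truth well-posedness choice: an untruncated exponential would
  occasionally plant accidental outliers among "baseline" tips, making the
  truth labels wrong by construction. The planted tips therefore satisfy
  the removal predicates exactly, and nothing else does.
* **Similarity matrix**: 100 models in 4 balanced communities; scores from
  a truncated normal on [0, 1] with σ = 0.05, mean 0.8 within and 0.2
  between communities — separable but non-degenerate at the 0.5 threshold.
* **DEG tables**: 600 orthogroups, two-thirds differentially expressed in
  both species, concordant with probability 0.62 (the published
  concordance observation, used as the planted condition); DEG genes get
  |log2FC| > 2 and adjusted p log-uniform in [10⁻¹⁰, 10⁻⁴], all other
  genes p log-uniform in [10⁻², 1], so the 10⁻³ cutoff separates them with
  margin. A 2 % fraction of orthogroups carries deliberately conflicting
  directions (mixed) and each species has five significant genes absent
  from the orthogroup map, exercising the exclusion paths.

All generators are pure functions of the configuration, including the
seed; the same configuration reproduces byte-identical output.

### What the benchmark does and does not show

The synthetic data validates the *procedures*: that classification
reproduces planted architectures exactly when hits are noise-free, that
the trimming rules flag precisely the planted branches, that Louvain
recovers well-separated planted communities, that motif scores rank
planted motifs essentially perfectly, and that the concordance estimator
is unbiased for the planted fraction. Real data differ in ways the
generator does not emulate: noisy and fragmented domain hits, alignment
error feeding the trees, structure-similarity scores with community
overlap and hubs, compositionally biased sequences, and many-to-many
orthology. Passing the benchmark therefore demonstrates correctness of the
implementations, not robustness to those noise sources; robustness is
governed by the upstream tools that produce the package's inputs.

## Numerical choices and degenerate inputs

Problem sizes in the tests and the acceptance script (trees ≤ 30 tips,
graphs of 100 nodes, 2,000-protein proteomes, 400-sequence scans) were
chosen as comfortable desk-scale workloads for a single CPU. Other
numerical conventions: occupancy and threshold comparisons are boundary
inclusive (≥) everywhere; tie-breaks are deterministic (documented per
function); an empty similarity graph has modularity 0 and yields the
all-singletons partition; an empty shared-orthogroup table gives an NaN
concordance with a warning rather than an error; p-distance pairs with no
comparable columns get distance 1; NJ trees clamp negative branch length
estimates to zero; cleaning stops with a warning status when fewer than
four sequences survive; and forward/Viterbi dynamic programming is carried
out in log2 space with max-shifted summation, so no underflow occurs at
realistic motif lengths.

## Known limitations

* The greedy clustering is order-dependent by design (longest-first); it
  is a transparent stand-in for production clustering tools, not a
  reimplementation of their heuristics.
* Louvain with restarts is a heuristic; optimality is verified exhaustively
  only on small graphs in the test suite.
* The cleaning loop's built-in p-distance/NJ tree builder underestimates
  long branches relative to model-based inference; with the default
  cutoffs this is conservative, and the hook accepts an external builder.
* Profile HMM scores are raw bits without E-value calibration and are not
  numerically comparable to HMMER output, though rankings agree for sharp
  N-terminal motifs.
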