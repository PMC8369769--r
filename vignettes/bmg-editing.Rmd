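---
title: "Heuristic best match graph editing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heuristic best match graph editing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(bmgedit)
```

## The model

A *best match graph* (BMG) is a vertex-colored digraph (G, σ) that arises
from a leaf-colored phylogenetic tree (T, σ): there is an arc (x, y) exactly
when, among all leaves of y's color, y has a lowest last common ancestor
with x. BMGs are characterized by two conditions:

1. σ is a *proper* coloring (no arc joins two vertices of the same color),
   and the set of **informative triples** — for each arc (x, y) and each
   non-arc (x, y′) with σ(y) = σ(y′) ≠ σ(x), the rooted triple xy|y′ — is
   consistent (displayed by a common tree);
2. the BMG of the Aho tree of those triples equals G itself
   (`recognize_bmg()` checks exactly this fixed-point condition and returns
   the least resolved explaining tree when it holds).

A BMG is *binary-explainable* when some binary tree explains it; this holds
iff every vertex has an out-neighbor of every other color present
("sf-colored") and the **extended triple set** — the informative triples
plus, for every *forbidden* triple xy|y′ (both arcs present), the triple
yy′|x — is consistent (`recognize_bebmg()`).

Real best-hit data violate these conditions, and the *editing problem* —
the minimum number of arc flips to the nearest BMG — is NP-complete. The
package implements the heuristics below.

## Top-down editing

`edit_topdown()` recursively splits the vertex set. On the current set V′:

1. Build the Aho graph of the informative triples (extended triples in
   binary mode) of the *current edited graph* restricted to V′.
2. If it is disconnected, take its connected components as the partition 𝒱.
   This short-circuit makes the algorithm **consistent**: on a valid input
   BMG it reduces to BUILD and performs no edits.
3. Otherwise obtain 𝒱 from a partitioning heuristic (below).
4. In binary mode, coarse-grain 𝒱 to a balanced bipartition.
5. Edit the **unsatisfiable relations** U(G, 𝒱) immediately and recurse on
   each block.

U(G, 𝒱) is the set of (non-)arcs contradicted by *every* tree whose root
split is 𝒱. It decomposes into three parts computable in O(|V|²):
arcs leaving a block toward a color present in the block (U1), missing arcs
leaving a block toward a color absent from the block (U2), and missing
within-block arcs toward a block-unique color (U3). The recursion yields a
tree T; by construction the output equals G(T, σ), the per-step edit sets
are pairwise disjoint, and the total cost is the sum of the per-step
UR-costs c(G, 𝒱) = |U(G, 𝒱)| — the test suite asserts all three
invariants on every run. The set U*(G) of missing arcs toward color-unique
vertices is contained in every edit set and provides a lower bound on any
heuristic's cost.

## Partitioning heuristics

All heuristics operate on the (connected) Aho graph H of the current step
and/or the induced colored digraph, and all randomized ones are wrapped in
`best_of()` which keeps the best of `runs` repetitions (default 5, matching
the recursion's default):

- **`mincut`** — exact Stoer–Wagner minimum edge cut of H. Deterministic;
  run once. Tends to split off single leaves, since a near-pendant vertex
  gives a small cut.
- **`karger`** — repeated random edge contraction (probability proportional
  to weight) down to two super-vertices; the candidate with the lowest
  UR-cost wins.
- **`greedy`** — grows one block from the empty set, always moving the
  vertex whose move minimizes the UR-cost of the implied bipartition; the
  best of the |V′| − 1 visited bipartitions is returned.
- **`gradient`** — starts from a uniformly random *balanced* bipartition and
  applies strictly improving single-vertex moves (ties broken at random,
  moves that empty a block forbidden) until locally optimal.
- **`louvain-m` / `louvain-c`** — two-phase Louvain community detection on
  H. Phase one repeatedly moves a vertex into a neighboring community when
  the objective improves, traversing vertices in random order; phase two
  contracts communities into a weighted quotient graph and repeats. The
  objective is either modularity (`-m`) or the UR-cost of the induced
  partition of the original vertices (`-c`). In *both* variants the move
  that would merge the last two communities is excluded, so the result is
  always a non-trivial partition.

### Numerical and design choices

- **Unnormalized modularity.** `graph_modularity()` returns
  Σ_W Σ_{u,v∈W} (a_uv − d_u d_v / 2m) over ordered pairs including u = v,
  i.e. 2m times the classical normalized score (the test suite pins down
  this relationship against igraph). Normalization does not affect the
  argmax, and the unnormalized form keeps the phase-one move deltas integral
  for unweighted Aho graphs.
- **UR-cost objective by full recomputation.** The `louvain-c` move
  evaluation recomputes c(G, 𝒱) in O(|V|²) per candidate instead of
  maintaining incremental color tables. At the problem sizes the package
  targets (tens of vertices per recursion step) this is well under a second
  per step and keeps the objective pluggable.
- **Gain function.** `gain(G, 𝒱)` counts the relations *settled in
  agreement* with G by the split. The package implements the literal
  "swapped membership" reading: the three UR-set definitions with "∈ E" and
  "∉ E" exchanged. On distinct-color pairs this coincides with the pairs
  forced to agree across all trees with root split 𝒱; in addition it counts
  every same-colored pair separated by the split (trivially a non-arc in
  any BMG), while same-colored pairs *inside* a block match no swapped
  rule. The tests assert exactly this characterization. The gain is
  provided for experimentation and is not used by the shipped strategies,
  as maximizing it tends to produce overly balanced partitions.
- **Degenerate-partition fallback.** If a heuristic errors or returns a
  trivial partition, the step retries (default 10×) and then falls back to
  a random balanced bipartition, so `edit_topdown()` always terminates.

## Triple-based editing and BPMF

`edit_triple_based()` first inserts the forced arcs U*(G) (`preinsert`,
default on), extracts the informative triples R, builds a guide tree —
either **BPMF** (bottom-up best-pair merging: every triple xy|z in three
distinct clusters scores +1 for merging the xy-pair and −1 for the two
outgroup pairs; the highest-scoring pair merges, ties at random) or a
top-down run — and keeps the displayed subset R* ⊆ R, which is consistent
by construction. The result is the BMG of the Aho tree of R*. BPMF is *not*
consistent: a regression test exhibits valid BMGs whose (consistent!)
informative triples are not all displayed by the agglomeration tree.

`edit(..., rebuild = TRUE)` reports both outputs of any method: the direct
result G(T, σ) and the rebuilt G(T*, σ) with T* = Aho(R*, V), which is
typically less resolved and often closer to the unperturbed truth.

### Binary-explainable editing

With `binary = TRUE` everything runs on the extended triple set, and any
partition with more than two blocks is coarse-grained to a bipartition by
largest-differencing (Karmarkar–Karp) **number partitioning** on the block
sizes — blocks are never split, and the two groups are as balanced as the
differencing heuristic achieves. The same coarse-graining inside BUILD
(`build_tree(coarsen = TRUE)`) turns the Aho tree into a binary tree. On a
valid binary-explainable input the procedure is again consistent.

## The instance generator

`make_benchmark_set()` emulates noisy best-hit estimation:

1. **Random tree growth** (`random_tree`): starting from a single leaf,
   each step attaches a new leaf either below a random inner vertex or by
   splitting a random leaf into a cherry; in binary mode only the latter,
   so the tree stays binary. This produces a mix of resolved and unresolved
   topologies rather than a fixed shape.
2. **Surjective coloring** (`random_coloring`): one distinct leaf per color
   first (so every color occurs), the rest uniform.
3. **Arc perturbation** (`perturb`): one independent pass over the ordered
   cross-color pairs, deleting each arc with probability `p_del` and
   inserting each non-arc with probability `p_ins`. Same-colored pairs are
   never touched — they cannot be best matches, and including them would
   only inflate specificity-type metrics.
4. **Retention filter** (`require_connected_aho`, default on): instances
   whose perturbed graph has a disconnected Aho graph are discarded, since
   the first recursion step would be trivial for every heuristic; the kept
   fraction is reported as the `retention` attribute. At two-sided 10%
   noise retention is a clear majority of generated instances.

The default benchmark size used in the acceptance material — 30 vertices,
10 colors, p_ins = p_del = 0.1, 30 instances — is the package's own choice:
large enough that heuristic quality differences are visible, small enough
that the full suite runs in minutes on one CPU.

## Evaluation metrics

`arc_symmetric_difference()` counts flipped relations; `arc_confusion()`
reports tp/fp/fn/tn and derived rates over the universe of ordered
distinct-color pairs (choice documented above). `run_benchmark()` ties
everything together, recording for each instance, method and output variant
the distance *d* to the noisy input, the distance *d_orig* to the true BMG,
confusion measures, the U1/U2/U3 breakdown, the fraction of recursion steps
splitting off a single leaf, and wall time. The headline qualitative
finding — at moderate noise the median *d_orig* is well below the median
*d* for the UR-cost Louvain method, i.e. editing recovers signal rather
than merely finding a nearby BMG — is asserted as a trend in the acceptance
tests and recomputed by `scripts/acceptance.R`.

## Limitations

- All editing methods are heuristics; even on three vertices the UR-based
  edit can cost twice the true optimum (see the README example). Exact
  minimization is NP-complete and only available here as exhaustive search
  over tiny trees in the test oracles.
- The UR-cost Louvain objective is recomputed from scratch per move;
  instances beyond a few hundred vertices would need an incremental
  implementation.
- Forbidden triples are not exploited in the general (non-binary) editing
  path.
- The generator perturbs arcs independently, which ignores the correlated
  error structure of real similarity searches; no real-data ingestion is
  included.
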