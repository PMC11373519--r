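---
title: "Genome ARGs: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome ARGs: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gargkit)
```

## The model

Under recombination, different parts of a genome follow different paths of
inheritance, so the genealogy of a sample of DNA sequences varies along the
genome. `gargkit` represents the whole structure as a *genome ARG*: a
directed acyclic graph whose nodes are haploid genomes and whose edges are
tuples $(c, p, I)$ recording that child genome $c$ inherited the set of
disjoint half-open intervals $I \subseteq [0, L)$ from parent genome $p$.
Nodes may carry a time $\tau_u$ (larger values further in the past) and a
sample flag; a subset $S$ of nodes is designated as the sample.

Two whole-graph invariants give the encoding its meaning:

* *acyclicity* — the child-to-parent relation admits a topological order,
  and when both endpoints of an edge are dated, the child is strictly
  younger;
* *per-child functional inheritance* — for any child $c$ and position $x$,
  at most one edge $(c, p, I)$ has $x \in I$. A genome inherits each site
  from at most one parent, so restricting the edge set to a position yields
  a forest: the *local tree* (or forest, where lineages do not fully
  coalesce within the graph).

We deliberately model only inheritance, not mutation or observed sequence:
the graph answers "who inherited what from whom", which is the substrate
every downstream computation needs. Structural variation is out of scope;
all genomes share one coordinate space. Coordinates are real-valued,
0-based and half-open, so integer breakpoints in examples are stored as
reals and adjacency (`[0,2)` next to `[2,10)`) is disjoint but merges under
union.

The classical alternative encodes *events* rather than genomes: internal
nodes are common-ancestor or recombination events, the latter annotated
with a crossover breakpoint. This event ARG (eARG) is supported as a
first-class input. Because a breakpoint alone cannot say which parent
transmits which side, the file format requires explicit `L`/`R` side labels
on the two out-edges of every recombination node; breakpoint-only dialects
would need extra ordering conventions that we do not invent. Conversion to
a gARG annotates the out-edge of every sample or common-ancestor node with
$[0, L)$ and the two out-edges of a breakpoint-$x$ recombination node with
$[0, x)$ and $[x, L)$; this is a bijection on the information content.
Gene conversion needs no third event type: on the gARG side it is simply an
edge whose interval set has two or more intervals.

## Local trees

`tree_at()` restricts the edge table to one position. `local_trees()`
recovers the full sequence of trees with a single left-to-right sweep:
every interval endpoint is a breakpoint, each edge is inserted at its left
end and removed at its right end, and the active child-to-parent map is the
local forest of the current region. The regions tile $[0, L)$ exactly, and
the sweep is checked in the tests against independent per-position
reconstruction.

Conventional drawings only show nodes where lineages coalesce. With
`suppress_unary = TRUE` the forest is restricted to the samples' ancestry
and *locally unary* nodes (one child at this position) are spliced out,
children re-attaching to the nearest retained ancestor; sample nodes are
never suppressed, and a root left with a single child is removed rather
than kept as a stalk. Both the retained and the suppressed form are
available, since conventions differ between tools.

`count_distinct_trees()` counts maximal runs of *adjacent* regions whose
suppressed forests are identical as child-to-parent maps. Identity is by
node id, not label-free topology: shared node identity across local trees
is precisely what the graph encoding adds over a list of trees, so two
topologically equal trees on different ancestors count as different.

## Ancestral material, resolution and the simplification ladder

The ancestral material of a node is the set of positions at which at least
one sample inherits through it. `ancestral_material()` computes it by
pastward segment propagation in the style of Hudson's simulation
bookkeeping: each sample seeds one segment $[0, L) \times 1$; segments are
clipped through edge intervals, merged at every node in time (else
topological) order, and counts add because each sample's inheritance at a
position follows a single path.

Two conventions exist for what happens above a position's MRCA, and the
package exposes both. Under the plain definition (`stop_at_mrca = FALSE`,
the default, and the semantics of the brute-force chain-following oracle in
the tests) material keeps propagating to the roots. Under the capped
convention (`stop_at_mrca = TRUE`) a position stops being tracked at the
node where all samples have coalesced — ancestry of entirely coalesced
regions is omitted. `garg_resolve()` uses the capped form: every edge's
intervals are intersected with the material its child propagates, empty
edges and then edge-less non-sample nodes are dropped. This is what makes
resolution remove a "grand MRCA" that sits above the last coalescence, and
it removes recombination edges whose breakpoint fell in nonancestral
material, as in the packaged `example_earg_trapped()`.

`garg_simplify()` applies resolution and then an optional ladder, each rung
preserving the samples' local genealogies at every position:

* **prune-diamonds** removes *singly connected* nodes: non-sample nodes
  with exactly one local child and one local parent at every position they
  cover, spliced out by intersecting child and parent intervals. This
  definition is deliberately the weakest per-position criterion that
  dissolves diamond-shaped path bundles; iterating to a fixed point removes
  whole bundles.
* **prune-unary** removes nodes whose coalescence span is zero — never two
  children carrying ancestral material at the same position — reconnecting
  children to grandparents. This is a strict superset of the previous rung.
* **full** rebuilds the graph from the suppressed local forests region by
  region, so surviving nodes appear in a local tree only where coalescent.

Node ids of the result are reassigned densely (samples first, then by time
and id) and a `node_map` table records the correspondence; resolution alone
keeps original ids so that idempotence is literal. Node counts and total
edge interval length are non-increasing along the ladder. The number of
distinct child–parent pairs can increase at the last rung (bypassing a
locally-unary stretch reroutes part of one edge to a grandparent), which is
why the monotonicity contract is stated on interval length, not edge-table
rows.

The binding contract for every rung — checked on the worked examples and on
batches of simulated graphs — is that the sample-restricted suppressed
forests, and hence all pairwise sample MRCAs, are unchanged at every
position.

The per-node *coalescence span* (`coalescence_span()`) is the fraction of
the genome over which a node has two or more child edges carrying ancestral
material. Spans strictly between 0 and 1 identify nodes that are coalescent
in some trees and unary in others, the structural signature that
distinguishes richer graphs from fully simplified ones.

## Simulators

The simulators exist to generate structurally varied, reproducible test
graphs; they are first-class, tested code, not fixtures.

`sim_wf_garg()` is a prospective diploid Wright–Fisher forward simulator.
Every genome of every generation becomes a node (inheritance is recorded
exhaustively, which is exactly what makes later simplification
informative). Per transmitted genome: the parent individual is uniform with
replacement (selfing allowed — the worked pedigree is itself highly
inbred), the crossover count is Poisson with mean `crossover_rate`,
breakpoints are uniform on $(0, L)$, and the transmitted genome alternates
between the parent's two genomes, so the inbound interval sets of every
non-founder partition $[0, L)$. Gene conversion draws a Poisson number of
tracts (uniform start, exponential length with mean `gc_tract_length`) and
flips the source genome within each tract. All draws come from one seeded
stream in a fixed order, so outputs are bit-identical across runs.
Founders have no parents and the final generation is the sample set. The
default example sizes (5 diploids, 6 generations, $L = 10$, one crossover
per meiosis) are chosen for visual tractability of the resulting graphs;
test batches use 50 such replicates, and the crossover moment check uses
500 diploids for 10 generations so that 10,000 meioses enter the estimate.

`sim_coalescent_earg()` is a backwards lineage process emitting an eARG:
$k$ lineages coalesce at rate $k(k-1)/2$; each lineage recombines at rate
`recombination_rate` scaled by the length of ancestral material it still
tracks, but the breakpoint itself is uniform on $(0, L)$. Uniform placement
means a breakpoint can fall outside the lineage's material, leaving one
side of the recombination node with nothing ancestral — the phenomenon that
resolution later erases. Scaling the rate by tracked material (which is
capped at full coalescence) guarantees the process cannot recombine
forever and terminates at a grand MRCA. Simulated sample sizes in the test
suite are 3–5 with $L = 10$: large enough to produce trapped material and
multiple local trees, small enough that 200 replicates with per-region
cross-encoding checks run in seconds to minutes.

## Numerical and design details

* Interval arithmetic is exact over doubles: no tolerances are used
  anywhere, and fixtures use integer-valued coordinates, so equality
  comparisons are safe. Endpoint collisions of random draws have
  probability zero and are not special-cased.
* Processing order for propagation is strictly by node time when every
  node is dated, otherwise by a Kahn topological sort with smallest-id
  tie-breaks, so outputs are deterministic and platform-independent.
  Equal child/parent times on an edge are a validation error; zero-length
  generations must be expressed through distinct times or absent times.
* A position exactly at a breakpoint belongs to the right-hand interval,
  consistently in traversal, conversion and membership tests.
* Degenerate inputs: empty interval sets are rejected at parse time (an
  edge with no inheritance carries no information); isolated nodes are
  legal; forests are returned as forests — no virtual super-root is
  invented where samples do not coalesce. A sample node may be an ancestor
  of another sample; nothing in the formal model forbids it, and counts
  simply add.
* Validation never throws on semantic problems: it returns a table naming
  the invariant and the offending ids, so malformed tables can be
  inspected. Only unreadable files raise errors, naming file and line.
* The canonical edge sort is (child time if present, child id, parent id,
  left endpoint); serialization is bit-exact under round-trip for
  canonical graphs.

## What the tests do and do not show

The property suite checks internal consistency (sweep vs per-position
reconstruction, segment propagation vs chain-following, event traversal vs
conversion) and the preservation contracts of resolution/simplification,
on hand-constructed worked examples and on simulated graphs from the two
generators. The generators produce neutral, panmictic, constant-size
populations with uniform recombination; real ARGs inferred from data have
polytomies, uncertain node ages, non-uniform recombination maps and error
processes that none of these fixtures emulate. Passing tests therefore
certify the algebra and the algorithms, not any statement about real-data
inference quality. Mutation overlay, selection, demography, tree-distance
metrics and inference from sequence are out of scope.
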