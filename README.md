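# gargkit

Tools for working with ancestral recombination graphs (ARGs) encoded as
**genome ARGs (gARGs)**: directed acyclic graphs whose nodes are haploid
genomes and whose edges carry the set of genomic intervals over which a
child genome inherited from a parent. Because recombination makes adjacent
parts of the genome follow different paths of inheritance, a single
genealogical tree cannot describe a recombining sample; the gARG stores the
full web of inheritance once, and the genealogy at any position falls out
of it.

The package is aimed at population-genetics practitioners who simulate,
convert, inspect or post-process ARGs, and at method developers who need a
small, fully-tested reference implementation of the core ARG operations.

## The encoding and its operations

A gARG is a pair of tables. Nodes are haploid genomes with an identifier,
an optional time (larger = further in the past) and a sample flag. Edges
are tuples *(c, p, I)*: child genome *c* inherited the half-open intervals
*I* ⊆ [0, L) from parent genome *p*. At every position each genome inherits
from at most one parent, so restricting the edges to a position yields the
local genealogical tree there, and interval endpoints are the only places
the genealogy can change.

On top of the data model the package implements:

- **Validation** (`garg_validate()`, `earg_validate()`): invariant checks
  that return a table of violations instead of throwing.
- **Event-ARG conversion** (`earg_to_garg()`): the classical encoding with
  common-ancestor and breakpoint-annotated recombination event nodes is
  converted by annotating the out-edges of a breakpoint-*x* recombination
  node with [0, x) and [x, L) and everything else with [0, L); the
  breakpoint-traversal construction of local trees (`earg_tree_at()`) is
  kept as an independent cross-check.
- **Local trees** (`tree_at()`, `local_trees()`, `count_distinct_trees()`,
  `forest_newick()`): a left-to-right sweep that inserts and removes edges
  at breakpoints, with optional suppression of locally-unary nodes.
- **Ancestral material and resolution** (`ancestral_material()`,
  `garg_resolve()`, `coalescence_span()`): Hudson-style pastward segment
  propagation; sample resolution intersects every edge with the material
  its child actually transmits, removing nonancestral annotation, edges
  whose material is empty, and structure above each position's full
  coalescence.
- **Simplification ladder** (`garg_simplify()`): resolve, then optionally
  prune singly connected path bundles ("diamonds"), remove nodes that are
  unary everywhere, or bypass locally-unary nodes region by region
  ("fully simplified") — all while provably preserving the samples' local
  genealogies.
- **Simulators** (`sim_wf_garg()`, `sim_coalescent_earg()`): a prospective
  diploid Wright–Fisher forward simulator (crossovers and gene conversion)
  and a backwards coalescent-with-recombination generator, both seeded and
  bit-reproducible.
- **I/O and presentation**: TSV table formats with bit-exact round-trips,
  DOT export, `tidy()`/`glance()` methods, `autoplot()`/`plot_local_trees()`
  figures, and a command-line wrapper (`inst/cli/gargkit.R`).

## Worked example

The packaged pedigree example is a gARG embedded in an inbred pedigree of
8 diploid individuals (16 genomes `A`–`P`, genome length 10). Samples
`A`–`D` are the current generation; `A` and `C` are recombinant products of
the parental genomes `E` and `F`, crossing over at positions 2 and 7.

```r
library(gargkit)
g <- example_garg_pedigree()
g
#> <garg> L = 10, 16 nodes (4 samples), 14 edges, 14 intervals

garg_breakpoints(g)
#> [1]  0  2  7 10

lt <- local_trees(g, suppress_unary = TRUE)
for (f in attr(lt, "forests"))
  cat(sprintf("[%g,%g): %s\n", f$left, f$right, forest_newick(f, g)))
#> [0,2): ((A,B)I,(C,D)K)N;
#> [2,7): (B,(D,(A,C)F)K)N;
#> [7,10): ((B,C)I,(A,D)K)N;
```

The two crossovers delimit three genomic regions, each with its own local
tree; in the middle region `[2,7)` samples `A` and `C` find a common
ancestor in genome `F`. The ancestral material confirms this: of the
parental generation `E`–`H`, only three genomes carry material ancestral
to the samples there, and `F` carries a doubly-inherited (coalesced)
segment over exactly `[2,7)`:

```r
am <- ancestral_material(g)
subset(am, node %in% 5:8)        # nodes E, F, G, H
#>   node left right sample_count
#>      5    0     2            1   # E: only [0,2) and [7,10) — blank in [2,7)
#>      5    7    10            1
#>      6    0     2            1
#>      6    2     7            2   # F: A and C coalesce here
#>      6    7    10            1
#>      7    0    10            1   # G carries B's genome
#>      8    0    10            1   # H carries D's genome

subset(coalescence_span(g), span > 0)
#>   node span
#>      6  0.5                     # F is coalescent over half the genome
#>      9  0.5
#>     11  1
#>     14  1
```

Converting the classical event-encoded example with a recombination whose
breakpoint falls in nonancestral material shows what resolution removes:

```r
e <- example_earg_trapped()       # samples A,B,C; breakpoint-5 node G
r <- garg_resolve(earg_to_garg(e))
setdiff(earg_to_garg(e)$nodes$id, r$nodes$id)
#> [1] 17                           # the grand MRCA Q is gone
```

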