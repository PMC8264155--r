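---
title: "Incremental linearization of genome sequence graphs"
author: "alibi package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental linearization of genome sequence graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alibi)
```

## The problem

A genome sequence graph represents a collection of similar genomes as a
bidirected graph: nodes carry DNA labels, each node has a left and a right
side (the 5′ and 3′ ends of its label), and edges attach to one specific side
of each incident node. Genome paths traverse the graph, entering every node
on one side and leaving on the other; the number of times paths traverse an
edge is that edge's weight.

A *linearization* jointly chooses, for every node, an orientation
$a(v) \in \{-1, +1\}$ (which strand of its label is primary, hence which side
is the in-side) and a position $\mathrm{ord}(v)$, a bijection onto
$\{1, \dots, |V|\}$. Relative to a linearization each edge is

* a **forward arc** — out-side to in-side, out node earlier,
* a **feedback arc** — out-side to in-side, pointing backward
  ($\mathrm{ord}$ of the out node $\ge$ that of the in node), or
* a **reversing join** — two in-sides or two out-sides (strand
  inconsistency).

Good layouts make the genomes read left-to-right: quality is measured by the
weighted totals WRJ (reversing joins) and WFA (feedback arcs), and by the
average cut width ACW — the mean number of edges spanning the $|V|-1$ cuts
between consecutive positions.

## The algorithm

The linearizer is greedy and incremental. Starting from singleton components
with all orientations $+1$, edges are inserted in decreasing weight order
(ties broken by the canonical edge key under C collation, so runs are
reproducible). Each insertion falls into one of six cases:

1. **Different components, one in- and one out-side.** The edge becomes a
   forward arc; the out-side node's component is placed before the other,
   positions of the second component shifted by $|V_1|$.
2. **Different components, like sides.** One component is reversed
   (positions $p \mapsto |V_1| + |V_2| + 1 - p$ within the concatenation,
   orientations negated) which turns the edge into an out-to-in edge; then
   merged as in case 1. Cross-component edges are therefore *always* forward
   arcs, and reversing a whole component never changes the class of any
   internal edge.
3. **Same component, like sides.** Orientations within a component are
   rigid, so the edge is recorded as a reversing join; nothing changes.
4. **Same component, out node already earlier.** A forward arc; nothing
   changes.
5. **Same component, in node earlier, and the in node reaches the out node
   through forward arcs.** The new edge would close a directed cycle: it is
   recorded as a feedback arc; nothing changes.
6. **Otherwise** the component is locally reordered (dynamic topological
   repair in the style of incremental topological-ordering algorithms): in
   the affected position window the set $V_F$ of nodes forward-reachable
   from the in node and the set $V_B$ of nodes reaching the out node are
   computed; their pooled positions are reassigned so all $V_B$ nodes
   precede all $V_F$ nodes, preserving the original relative order inside
   each set. All other positions are untouched, no orientation changes, and
   every previously recorded class survives. The edge becomes a forward arc.

Since forward arcs always point from smaller to larger positions, the
forward arcs form a DAG topologically sorted by $\mathrm{ord}$ at every
step, and the classes recorded at insertion time can be re-derived verbatim
from the final layout — a property the test-suite checks on every run.

Disconnected components are concatenated in order of their smallest node
index; isolated nodes ride along as singletons. The heuristic carries no
optimality guarantee, but on chains, trees and single cycles it provably
attains the optimum (trees incur no adverse edge at all; a cycle sacrifices
exactly its lightest edge), which the suite verifies against an exhaustive
enumerator.

## The augmented disjoint-set forest

Components, orientations and positions are maintained in a union-find
forest with three per-node attributes relative to the parent: `orient`
($\pm 1$), an inheritable position offset `shift`, and a non-inheritable
final offset `reorder_shift`. A node's actual orientation is the product of
`orient` over it and its ancestors; its actual position is the sum of the
ancestors' `shift` times their actual orientations plus its own
(`shift` + `reorder_shift`) times its own orientation.

Writing $S(v) = P(v) - \mathrm{reorder\_shift}(v) \cdot A(v)$ for the
inheritable prefix, the recurrences are $A(c) = A(p)\,\mathrm{orient}(c)$
and $S(c) = S(p) + \mathrm{shift}(c) A(c)$. Re-parenting a node $x$ under a
root $r$ without moving anything therefore requires exactly

$$\mathrm{orient}'(x) = A(x)A(r), \qquad
  \mathrm{shift}'(x) = \bigl(S(x) - \mathrm{shift}(r)A(r)\bigr)A(x),$$

which is the closed-form composition used during path compression. This
derivation was validated against an explicit shadow implementation (plain
orientation/position arrays rewritten wholesale at every operation) by
randomized fuzzing *before* the main algorithm was built on top of it, and
the fuzz — $10^4$ operations with every observation compared after every
operation — remains in the suite.

A merge applies an affine transform $P \mapsto \varepsilon P + \delta$
(with $\varepsilon$ also multiplying orientations) to each component by
editing attributes at the two roots only; union by rank decides the tree
shape and the attribute arithmetic compensates for whichever root wins, so
the amortized near-constant union-find cost is preserved. An
instrumentation counter asserts that a merge touches at most two entries.
Positions are kept as doubles (exact for integers below $2^{53}$, far
beyond any graph this package will see); shifts can be negative internally
because reversals negate subtree contributions. Within every component the
actual positions always form exactly $\{1, \dots, \text{size}\}$ — slightly
stronger than an arbitrary contiguous interval, chosen for testability.

## GFA conventions

Input and output are GFA1 (`S`/`L`/`P` records; GFA2 and `W` walks are
rejected with a clear error, other record types are skipped with a
warning). A link's strands map to sides via the traversal convention: a
`+` visit is left on the right side and entered on the left. Edges are
stored canonically (endpoints sorted by node id and side under C
collation), so the same bidirected edge written from either strand
collapses to one record. Weights are the path-traversal counts; a file with
no `P` lines gets uniform weight 1, and with paths present an uncovered
edge gets weight 0 — it is processed last but still classified. An optional
numeric link tag can override path weights for graphs distributed without
paths (off by default). When writing a linearized graph, nodes oriented
$-1$ are emitted reverse-complemented with all link/path references strand
flipped, so every path spells the identical DNA string before and after —
asserted byte-exactly in the tests.

## The simulator

`simulateGenomes()` emulates a standard pangenome simulation protocol: a
uniform random reference fragment (default 37 287 bp) receives, per genome
(default 10), a fixed number $k$ of deletions, insertions, inversions and
tandem duplications with default lengths 20, 20, 200 and 500 bp, at
uniformly drawn non-overlapping loci (the interesting experimental range
for $k$ is roughly 5–11 per type). Variant loci are drawn independently per
genome; placements touching another variant's boundary are rejected so the
event order at every breakpoint is well defined.

`buildVariantGraph()` then constructs the graph *exactly* from the known
breakpoints rather than by multiple alignment: the reference is segmented
at the union of all genomes' breakpoints, plus a regular grid every
`maxNodeLength` (default 1000 bp) emulating the node-length capping of
practical graph constructors — this also makes the variant-free case a
non-trivial chain rather than a single node. Deletions skip segments,
inversions traverse their segments in reverse on the `-` strand,
duplications revisit their segments (inducing a tandem back edge rather
than new nodes, which exercises cycle handling), and insertions get their
own nodes. Every edge arises from a path adjacency, so the path cover is
complete by construction, and concatenating strand sequences along each
path must reproduce the rearranged genome byte-exactly — the end-to-end
correctness check for both operations.

What this emulates — and what it does not: graphs here have exact
breakpoints and no alignment noise, no SNVs, no microhomology at
breakpoints, and no collapsed repeats. Passing tests on these graphs show
the algorithm and metrics behave correctly on clean pangenome topologies
(including cycles and strand flips); they say nothing about the messier
node structure an aligner-built graph of real genomes would have.

## Numerical and design choices

* **Tie-breaking.** Equal-weight edges process in canonical-key order;
  determinism is required for the bit-exact equivalence between the
  incremental implementation and the naive reference.
* **Initial orientation** is $+1$ everywhere; any fixed choice is valid.
* **Self-edges** are not covered by the classification rules above: an
  out/in self-loop is recorded as a feedback arc (a node cannot precede
  itself) and a like-sided self-loop as a reversing join — the only
  classifications consistent with the definitions. Self-edges never cross a
  cut, so they do not contribute to ACW.
* **Feedback detection** is fused into the $V_F$ search (abort on reaching
  the out node); the partial visit set of an aborted search is discarded.
* **ACW** counts each edge once by default (a weighted variant sits behind
  a flag); cuts between components are counted like any other cut.
* **Degenerate inputs.** An empty graph is an error; an edgeless graph
  linearizes to the identity layout; a single node has ACW 0.

## Problem sizes used in the suite

The randomized equivalence suite runs 200 graphs of up to 50 nodes and 120
edge draws; the exhaustive comparisons use 100 graphs of at most 6 nodes
(the enumerator is guarded at 8); the forest fuzz performs $10^4$
operations; and the simulation tests run the full protocol grid
($k = 5,\dots,11$, 10 genomes, 37 287 bp) plus the variant-free and
inversion-only controls. These sizes keep the whole suite within a few
minutes on one CPU while covering every code path; all quantities the
vignette mentions are recomputed by the tests, not quoted.

## Known limitations

* The linearizer is a heuristic: no minimization guarantee for WRJ/WFA and
  no attempt to optimize ACW directly.
* Graph construction from raw sequences (alignment) is out of scope; input
  graphs come from GFA1 or from the exact simulator.
* The forest is an in-memory structure without serialization or
  concurrency guarantees.
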