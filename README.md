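# alibi — incremental linearization of genome sequence graphs

Pangenome references are often stored as *genome sequence graphs*:
bidirected graphs whose nodes carry DNA labels, whose edges attach to a
specific side (5′ or 3′) of each incident node, and whose genome paths
traverse every edge, weighting it by its traversal count. Such a graph is
far easier to visualize, index and coordinate once it is *linearized* —
every node given an orientation `a(v) ∈ {−1, +1}` (which strand is primary,
hence which side is the in-side) and a position `ord(v)`, a bijection onto
`1..|V|`. Relative to `(a, ord)` every edge is a **forward arc** (out-side
to in-side, out node earlier), a **feedback arc** (out-to-in pointing
backward) or a **reversing join** (two in-sides or two out-sides). Layout
quality is summarized by

* **WRJ** — total weight of reversing joins,
* **WFA** — total weight of feedback arcs,
* **ACW** — average cut width: the mean number of edges spanning the
  `|V|−1` cuts between consecutive positions.

This package implements the incremental linearization algorithm ALIBI:
edges are inserted in decreasing weight order into an augmented
disjoint-set forest that tracks components, orientations and positions
with near-constant amortized updates; cross-component edges always become
forward arcs (reversing one component when the edge joins two like sides),
and within-component order conflicts are repaired by a dynamic
topological reordering so that heavy edges end up forward whenever
possible. The package also provides GFA1 input/output, the three metrics,
and a structural-variant simulator that builds pangenome-style graphs with
known ground truth. It is aimed at people building or evaluating pangenome
graph tooling.

## Worked example

Simulate ten genomes from a 37,287 bp reference with five deletions,
insertions, inversions and tandem duplications each (lengths 20, 20, 200,
500 bp), build the exact variation graph, and linearize it:

```r
library(alibi)

sim <- simulateGenomes(refLength = 37287, variantsPerType = 5,
                       nGenomes = 10, seed = 7)
g <- buildVariantGraph(sim$reference, sim$variants)
g
#> BidirectedGraph: 436 nodes, 685 edges, 11 paths
#>   total edge weight: 4506

lin <- linearizeGraph(g)
rep <- metricReport(g, lin)
cat(sprintf("WRJ = %g, WFA = %g, ACW = %.3f\n", rep$wrj, rep$wfa, rep$acw))
#> WRJ = 100, WFA = 50, ACW = 2.867
```

Reading: after linearization, edges carrying a total weight of 100 still
join inconsistent strands (reversing joins — inversions make some of these
unavoidable), weight 50 points backward (feedback arcs — duplications
induce cycles, and every cycle must break somewhere), and an average of
about 2.9 edges cross each cut between consecutive nodes. The heavy
path-following edges are all forward. `writeGFA(g, "out.gfa", lin = lin)`
writes the reordered, re-oriented graph; every path spells the identical
DNA before and after.

A shell interface is installed with the package (`exec/alibi`):

```sh
alibi generate -o sim.gfa --seed 7 --variants-per-type 5
alibi linearize sim.gfa -o sim.lin.gfa --report edges.tsv
#> wrj   wfa   acw
#> 100   50    2.86738
alibi score sim.lin.gfa
```

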