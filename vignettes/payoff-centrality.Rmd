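---
title: "Payoff centrality for signed weighted networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Payoff centrality for signed weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atria)
```

## The model

The package ranks nodes of a signed, weighted, undirected network — the
motivating case being bacterial co-occurrence networks, where nodes are taxa
and edge weights in $[-1,1]$ are co-occurrence correlations (positive:
cooperation, negative: competition).  Classical centralities each miss part
of what matters in such networks: degree and eigenvector-style scores crowd
into the densest club, closeness smears over one region, and betweenness
sees bridges but not leaders or villains.

The centrality used here is an economic payoff.  For a pair of nodes $i,j$,
the *gain* $G(i,j)$ is the largest positive product of edge weights over all
simple paths between them, and the *loss* $L(i,j)$ is the most negative such
product (either is 0 when no path of that sign exists).  A path pays the
product of its weights, so a path with an even number of negative edges is a
gain and an odd number a loss; because $|w| \le 1$, the contribution decays
with path length, generalizing the uniform-weight payoff $\delta^{t_{ij}}$
of network-formation games to non-uniform, signed weights.  A node's pay is

$$u_i = \Big|\sum_{j \ne i} G(i,j) + L(i,j)\Big|,$$

the magnitude of its net benefit to (equivalently, in a symmetric network,
from) everyone else.  Disconnected pairs contribute exactly zero, so the
score is well defined on fragmented networks, unlike closeness; and
$u_i \le n-1$ always.

Three roles fall out of the sign structure.  A *leader* has strong positive
connections and large positive signed pay; a *villain* holds strong negative
edges against a club and gets a large-magnitude negative signed pay; a
*bridge* connects clubs and collects moderate pay from several of them.

## Iterative extraction with triad ablation

Computing pay once and sorting would crowd the top ranks around the first
winner (its neighbors inherit most of their pay from it).  Instead the
procedure is iterative:

1. compute the pay vector on the current graph;
2. extract the node with maximum pay, recording its pay *at selection*;
   ties go to the lexicographically smallest identifier (a deterministic
   refinement of an arbitrary choice);
3. ablate the extracted node: using a snapshot of its incident edges, for
   every pair of its neighbors $a,b$ whose triad through $v$ is
   *structurally stable* — an even number of negative edges, i.e.
   $\mathrm{sign}\,w_{av}\,\mathrm{sign}\,w_{bv} = \mathrm{sign}\,w_{ab}$ —
   the third edge $(a,b)$ is deleted; then $v$ and its incident edges are
   removed.  All pairs are judged against the snapshot at once, with no
   cascading;
4. repeat until the maximum pay is zero; remaining nodes are appended with
   zero pay.

The ablation rule encodes balance theory: two nodes sharing a friend (or an
enemy) tend to be friends, and two nodes on opposite sides of $v$ tend to be
enemies, *because of* $v$ — those edges are coincidental and must not keep
paying the neighborhood after $v$ has been credited.  Note that the rule
covers both stable configurations: same-sign incident edges with a positive
third edge, and opposite-sign incident edges with a negative third edge.
Restricting it to the first case would leave the rival-groups clique (below)
with spurious nonzero centralities after the first extraction.

```{r ablation}
tri <- signed_graph(data.frame(from = c("A", "A", "B"),
                               to   = c("B", "C", "C"),
                               weight = c(0.9, 0.8, 0.7)))
igraph::ecount(ablate_node(tri, "A"))  # stable triad: B-C removed too
```

## Computing gain and loss exactly

The gain/loss labels are propagated by a modified relaxation: a positive
edge $(j,k)$ updates gain from gain and loss from loss; a negative edge
swaps them.  A subtlety the package takes seriously: plain label-correcting
over *walks* is not sound for the simple-path definition.  If the graph
contains a cycle whose edge-sign product is negative (an "odd" cycle), a
walk can absorb that cycle to flip its sign and beat every simple path — for
instance a single negative edge into an odd triangle yields a positive walk
product to a node that no positive *simple* path reaches.  The engine is
therefore an exact best-first search over labels that carry their visited
set, with two sound prunes:

* **dominance** — a label is dropped when another label at the same node
  with the same sign has at least its magnitude and a subset of its visited
  set;
* **bound pruning** — walk-product upper bounds $M^+(v,j)$, $M^-(v,j)$,
  computed as one all-pairs Dijkstra on the *signed double cover* of the
  graph (two copies of each node; positive edges stay within a copy,
  negative edges cross), certify when no extension of a label can strictly
  improve any current label, at which point it is discarded.  Walks are a
  superset of simple paths, so the bound is valid; and a label pruned this
  way can only produce values already attained, so exactness is preserved.

Termination is guaranteed by the finiteness of simple paths even when
$|w| = 1$ plateaus are present (the package admits the closed endpoints
because correlation networks reach them).

When every component is *balanced* — no cycle with an odd number of negative
edges, detected for free from the double cover (a node's two copies are
never connected) — all paths between a fixed pair share one sign, and
deleting a cycle from a walk never shrinks the product.  The double-cover
bounds are then attained by simple paths and are themselves the exact
labels, so the whole pay vector reduces to row sums of one Dijkstra pass.
All-positive networks, the rival-groups clique and the five-club network are
balanced, which is what makes the larger benchmarks fast; general mixed-sign
networks fall back to the exact search.  Both routes are checked against an
exhaustive simple-path enumeration (`brute_force_gain_loss()`, capped at 10
nodes by default) in the test suite, to an absolute tolerance of $10^{-12}$;
no floating-point tolerance is applied inside the relaxation itself.

## Baselines

For comparison the package carries the classical trio, adapted to signed
weights the standard way: *weighted degree* is the signed sum of incident
weights (so villains score low — an absolute-value variant is available
behind a flag); *closeness* and *betweenness* run on the distance transform
$d = -\ln|w|$, under which stronger ties are shorter and minimum-sum
distances coincide with maximum-$|$product$|$ paths.  Closeness is
component-restricted (reciprocal of summed distances to reachable nodes,
isolated nodes scoring 0).  Eigenvector-family scores for signed graphs
(PageTrust, PN) are deliberately absent: they are other methods'
contributions, not this package's.

## Synthetic network families

Every benchmark network is generated in code, seeded and parameterized, with
planted roles recorded so claims are testable without downloads:

* `clique_with_leader(n)` — positive clique; the leader's edges are drawn
  from a strictly higher range (defaults $[0.9,0.95]$ vs $[0.7,0.8]$).
* `clique_with_villain(n)` — positive clique plus a common enemy with
  edges in $[-0.95,-0.9]$.
* `rival_groups(sizes, w)` — complete graph, $+w$ within groups, $-w$
  across; deterministic.
* `two_triads()` — two positive triangles joined by one weak connector
  (C–E).  The structure this emulates has two clear local leaders, so the
  leader's two edges are drawn from the upper third of the triad's weight
  range and the remaining edge from the lower third; with the default
  connector 0.1, the leader's guaranteed margin (a third of the range
  width, 0.033) strictly exceeds the largest possible connector relay to
  the bridge endpoint ($c\,(1-w_{BC})(1+S_2) \le 0.022$ for triad one, and
  $c\,(1-w_{DE}) \le 0.023$ for triad two after the first ablation), so the
  two leaders are extracted first for *every* seed, not merely on average.
  A dominant connector instead hands rank 1 to an endpoint: the one in the
  tighter triad when positive, the other one when negative.
* `two_cliques(10, 100)` — disjoint cliques, i.i.d. uniform $(0,1)$
  weights.
* `five_club_network()` — five cliques of sizes 16–20; three planted
  leaders (edges $[0.85,1)$), two planted villains ($(-1,-0.85]$);
  member–member edges between 0.75 and the lower of the two endpoints'
  planted-edge magnitudes; $\lceil\max\text{size}/2\rceil$ bridges, each
  linking one ordinary member in each of two distinct cliques with weights
  $[0.75,1)$.  Bridge hosts are drawn *without replacement across bridges*:
  a member hosting two bridge endpoints would itself be a bridge in all but
  name, making the planted labels — the whole point of the generator —
  ill-defined.
* `scale_free(n, m)` — preferential attachment with uniform $(0,1)$
  weights, the canonical hub-dominated model.

## What the generators do and do not show

The generators emulate the *topology and weight structure* of the study
networks: planted dominance hierarchies, sign structure, club-and-bridge
architecture, hub tails.  They do not emulate features of real
co-occurrence networks such as correlated noise on weights, compositional
artifacts of relative-abundance data, or missing edges from undersampling —
so a passing suite shows algorithmic correctness on the intended structures,
not robustness of the method on noisy field data.

Two honest limitations surface even on the clean structures.  In the
five-club network, a member whose edge to its leader is close to 1 and who
hosts a strong bridge can out-pay the leader by a near-zero margin — both
quantities scale with $(1-w_{mL})$ — and extracting that member first
ablates every leader edge (all leader–member–member triads are stable),
zeroing the leader; with the stated weight ranges this happens for a small
fraction of seeds, so exact planted-set recovery is the typical but not the
universal outcome.  In the scale-free family at the desk scale used here
($n = 200$, $m = 2$), uniform $(0,1)$ weight jitter occasionally lets a
well-weighted mid-degree node out-pay the raw-degree hubs; hub dominance
strengthens with size.

## Numerical and design choices

* Node identifiers are opaque strings; every ordering (tie-breaks,
  appended zero-pay nodes, outputs) is lexicographic by code point, so runs
  are bit-reproducible.
* Zero-weight edges are rejected, not dropped: a zero correlation should be
  an absent edge, and anything else in the input is a data error.
* Duplicate undirected pairs, self-loops and $|w| > 1$ are errors with the
  offending line reported.
* The reported centrality is the pay at the iteration of selection — the
  procedure recomputes pay after each ablation, and the recomputed value is
  the one that made the node win.
* Ties between equal-product paths are irrelevant to pay (only the value
  enters) and are not tracked.
* Problem sizes in the shipped tests: oracle equivalence on 100 random
  graphs of 5–9 nodes; 20 five-club instances (88–110 nodes); ten
  200-node scale-free instances.  These sizes exercise every code path
  (exact search, balanced closed form, ablation cascades) while keeping the
  default suite quick.

## Limitations

Directed networks are out of scope (the payoff symmetry argument breaks).
Bridges are observable as nonzero-pay non-leaders but carry no formal
detection rule.  The iterative procedure costs up to $n$ pay recomputations;
the balanced closed form makes that cheap on balanced networks, while
worst-case unbalanced dense graphs fall back to the exponential-in-principle
exact search, kept practical by the double-cover bounds.
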