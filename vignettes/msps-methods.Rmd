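---
title: "Maximum-scoring path sets: models, algorithms and design choices"
author: "msps package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-scoring path sets: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msps)
```

## The problem

Many genomic analyses end with a vector of per-position scores — log-odds of
CpG islands, ChIP-seq enrichment, mutation density — and ask for the
high-scoring stretches. The classical sequence formulation assigns weight
$w_i$ to position $i$ and a startup penalty $c \ge 0$ per reported segment,
and maximizes
$$\sum_{\text{segments } S} \Big( \sum_{i \in S} w_i - c \Big),$$
over sets of disjoint segments. The penalty controls granularity: small $c$
yields many short segments, large $c$ merges neighbouring segments across
low-scoring gaps and drops weak ones.

`msps` generalizes this from sequences to *vertex-weighted graphs*, the
natural setting for pangenomes, where a graph represents many related genomes
at once and every haplotype is a path. Given a directed or undirected graph
$G$ with vertex weights $w(v)$ and a penalty $c \ge 0$, a path
$\pi = u_1,\dots,u_\ell$ scores
$$w(\pi) = -c + \sum_{j=1}^{\ell} w(u_j),$$
and the task — *maximum-scoring path sets* (MSPS) — is to pick vertex-disjoint
simple paths maximizing $\sum_i w(\pi_i)$. A single vertex is a legal path of
length zero. On general graphs the problem is NP-hard (with unit weights and
$0 < c < n$, a solution of score $\ge n - c$ exists exactly when the graph
has a Hamiltonian path — one of the test suite's sanity checks), so the
package solves it exactly on graph classes with small treewidth, where linear
time in the graph size is possible.

## The solvers

### Sequences: `solve_sequence()`

For a path graph the two-state scan applies: $M[i,1]$ ($M[i,0]$) is the
optimum over the first $i$ vertices with $v_i$ used (unused),
$$M[i,0] = \max\{M[i-1,0],\, M[i-1,1]\},\qquad
  M[i,1] = \max\{M[i-1,0] + w_i - c,\, M[i-1,1] + w_i\},$$
with $M[1,0]=0$, $M[1,1]=w_1-c$ and answer $\max\{M[n,0],M[n,1]\}$. A new
segment opens only after an unused vertex: adjacent segments could otherwise
be merged, saving one penalty. Reported intervals are 0-based half-open
(internally the recurrence is 1-based); tie-breaks prefer the unused state,
so among optima the reported one covers the fewest vertices.

### Series-parallel graphs: `solve_ttsp()`

Two-terminal series-parallel (TTSP) directed graphs are built from single
edges $(s,t)$ by series composition (merge $t_1 = s_2$) and parallel
composition (merge sources and targets). They come with a binary
decomposition tree whose nodes are modules $H$ with terminals $s,t$; elastic
degenerate strings (EDS), a common pangenome representation, convert directly
into this class (`eds_to_ttsp()`): every alternative of a degenerate symbol
becomes a chain of one-character vertices between flanking auxiliary vertices
of weight 0, alternatives compose in parallel, symbols in series, and nested
symbols expand recursively with the same flanking rule. The package fixes a
concrete EDS syntax (`"A{C,G}T"`, empty alternatives as `"{A,}"`, arbitrary
nesting) since the notation in the literature is informal.

The DP keeps four values per module, $M[H,u_s,u_t]$, indicating whether each
terminal is used. For an edge module these are $0$, $w(s)-c$, $w(t)-c$,
$w(s)+w(t)-c$ (when both terminals of a single edge are used, connecting them
into one path dominates two singletons since $c \ge 0$). A series composition
over the merged vertex $t_1$ takes
$$M[H,u_s,u_t] = \max\{M[H_1,u_s,0] + M[H_2,0,u_t],\;
  M[H_1,u_s,1] + M[H_2,1,u_t] - w(t_1) + c\},$$
the second row removing the double-counted weight of $t_1$ **and** the
double-charged penalty: both subproblems priced the path through (or the
singleton at) $t_1$, and after merging exactly one of those path starts
survives. The sign of the penalty correction matters; the two-unit-edge chain
with all weights 1 and $c = 1$ must give $M[H,1,1] = 2$, which pins it down,
and the oracle-equivalence tests confirm it across random instances. Parallel
composition lets each terminal be used by at most one side (a terminal of a
directed TTSP module has edges in only one direction, so it cannot join paths
from both sides), giving 1, 2, 2 and 4 candidate combinations for the four
states. Undirected TTSP graphs are *not* given a bespoke module DP; they are
handled by the general treewidth solver below via the same decomposition
(the module tree converts to a width-2 tree decomposition either way).

### Bounded treewidth: `solve_treewidth()`

A tree decomposition of $G$ is a tree of bags $X_i \subseteq V$ such that
every vertex appears in a bag, every edge has both endpoints in a common bag,
and the bags containing any vertex form a connected subtree; its width is
$\max_i |X_i| - 1$. Two constructions ship with the package:

* `ttsp_to_tree_decomposition()`: one bag per module-tree node — edge and
  parallel bags $\{s,t\}$, series bags $\{s,t_1,t\}$ — width $\le 2$;
* `from_path_cover()`: for a DAG whose edges are covered by $k$ paths (a
  pangenome built from $k$ sequences always has such a cover), a *path*
  decomposition of width $\le k$: in topological order, bag $X_i$ holds $v_i$
  plus each cover path's most recent earlier vertex. The topological order
  uses Kahn's algorithm with lexicographic tie-breaking, making the
  construction reproducible; the diamond DAG `1→2→4, 1→3→4` covered by
  `(1,2,4)` and `(1,3,4)` yields bags `{1}, {1,2}, {1,2,3}, {2,3,4}`.

Computing an optimal-width decomposition is itself NP-hard and out of scope;
the solver consumes whatever decomposition it is given (including the trivial
single-bag one, `single_bag_td()`, useful for testing on small graphs).

**Preprocessing** (`preprocess()`) reshapes the instance so that a candidate
solution is just a set of edges in which each vertex has at most one incoming
and one outgoing selected edge (undirected: at most two incident edges) —
i.e. a disjoint union of paths *and cycles*; a cycle can always be opened
into a path of equal score by dropping an edge, so allowing cycles loses
nothing. Because the edge-set view cannot express single-vertex paths, every
vertex $v$ with $w(v) \ge c$ gains a pendant twin $v'$ of weight 0, an edge
$(v,v')$, and a leaf bag $\{v,v'\}$ attached to the bag containing $v$
nearest the root (any holder is correct; the root-most is fixed for
determinism): selecting $(v,v')$ later converts back to the singleton $(v)$.
The tree is rooted at bag 1, bags with more than two children are duplicated
into a left-leaning chain, and empty leaves are appended so every nonempty
bag has exactly two children. Each edge is assigned to the unique root-most
bag containing both endpoints, and each bag's *terminals* are its
intersection with its parent — the only vertices its subtree shares with the
rest of the graph. These steps keep the decomposition valid, raise the width
at most to 1 (for the pendant pairs) and at most quadruple the bag count: the
package asserts `bags ≤ 4 × (original bags + auxiliary vertices) + 1`, the
binarization chain and the two empty children per leaf being the drivers.

**Configurations.** The DP runs bottom-up. For a bag $X$ with terminal set
$T$, a *configuration* gives each terminal two slots (incoming/outgoing for
directed graphs; two symmetric slots otherwise); a used slot points to the
first terminal reached along its path, or to a NONE marker when the path
never returns to $T$. That is at most $|T|+2$ values per slot and
$(|T|+2)^{2|T|}$ configurations. $M[X,C]$ is the best score achievable using
only the edges assigned within $X$'s subtree while crossing $T$ exactly as
$C$ prescribes. Internal bags are evaluated through *extended
configurations*: two slots for every bag vertex, each recording its origin
(left subtree, right subtree, bag edge, unused) and its pointer to the next
bag vertex — at most $(3|X|+4)^{2|X|}$ candidates. An extended configuration
$E$ scores
$$M'[X,E] = M[X_1,C_1] + M[X_2,C_2] + \Delta w + \Delta c,$$
where $C_i$ is the unique child configuration consistent with $E$
(`ec_child_conf()`), $\Delta w$ adds weights of vertices first used by bag
edges and subtracts those used in both subtrees (`ec_weight_delta()`), and
$\Delta c$ subtracts one penalty per connected component of the slot-pointer
structure over $X$ and adds back one per component visible in each child
configuration, whose penalty the child already paid (`ec_penalties()`).
Components entirely inside a subtree never surface and keep their penalty.
Component counting treats the pointer structure as an undirected auxiliary
graph and counts connected components with union–find; this uniformly covers
open paths, paths touching the bag several times, and closed cycles through
the bag (a closed cycle is one component, charged one penalty, later opened
into a path at no cost). $M[X,C]$ is the maximum of $M'[X,E]$ over consistent
$E$ (`ec_reduce()` chases pointers through non-terminal vertices to find each
slot's first terminal). Empty leaves hold the single empty configuration with
score 0, and the root — which has no terminals — holds a single entry: the
optimum. Traceback stores, per table entry, the best pair of child entries
plus the selected bag edges; `postprocess_solution()` then opens cycles,
strips the auxiliary twins and emits vertex-disjoint paths on the original
graph.

**Enumeration strategy.** The compiled solver does not filter all
$(3|X|+4)^{2|X|}$ candidates. Every extended configuration with a finite
score is the combination of one *reachable* configuration from each child
table and one degree-feasible subset of the bag's assigned edges, and every
such slot-disjoint combination is valid by construction; the solver
enumerates exactly those triples. Unreached configurations are simply absent
from the tables — the infeasible marker is table absence, never a large
negative number, so no sentinel can leak into arithmetic. The R-level
`enumerate_extended_configs()` builds candidates without child tables (used
by the bound checks); both counts are asserted against the
$(3|X|+4)^{2|X|}$ and $(|T|+2)^{2|T|}$ limits in the tests.

### The oracle: `solve_bruteforce()`

Exhaustive enumeration of degree-feasible edge subsets with the same
path-and-cycle scoring plus optional singletons, guarded to 18 edges. The
test suite double-checks it against a second, structurally different oracle
that enumerates sets of vertex-disjoint simple paths directly, then uses it
to verify all other solvers on hundreds of seeded instances.

## Determinism and numerics

* Vertex identifiers are opaque strings ordered by radix sort; all
  tie-breaking (cycle opening at the lexicographically smallest edge,
  traceback preferences, topological order) derives from that order, so
  results are reproducible across platforms and locales.
* Ties between solutions of equal score are broken toward the
  first-encountered candidate under a fixed enumeration order (children's
  table insertion order, then edge subsets in increasing bitmask order); in
  practice this prefers smaller solutions, e.g. a vertex with $w(v) = c$ is
  left out rather than reported as a zero-score singleton.
* Scores are doubles. With integer weights and penalties in
  $\{0, 0.5, 1, 2\}$ every partial sum is exactly representable, so the
  equality tests across solvers are exact; for general real weights the
  internal consistency checks use an absolute tolerance of $10^{-9}$.
* The compiled solver packs a bag configuration into a 64-bit key (4 bits per
  slot), which caps terminals per bag at 8 and bag size at 12. This is a
  deliberate envelope: the table bound $(t+2)^{2t}$ makes wider
  decompositions computationally useless long before the cap binds, and the
  solver fails with a clear message rather than thrash.

## Synthetic data

All tests and the acceptance script run on generated instances
(`generate_random_instance()`); nothing is downloaded. The generator kinds
mirror the graph classes above: weight sequences (`path`), random trees with
their width-1 bag-per-edge decompositions (`tree`), random series/parallel
compositions (`ttsp`), DAGs merged from $k$ random increasing vertex
sequences over a shared pool, returned with their covering paths
(`dag_from_paths`, emulating a pangenome DAG built from a multiple alignment
of $k$ sequences), and arbitrary density-controlled graphs (`generic`).
Default weights are integers uniform on $[-3, 3]$: with penalties of order 1
this regime forces real decisions — bridging negative gaps, dropping weak
islands — rather than degenerate all-positive or all-negative instances.
Every generator is a pure function of its seed.

What the synthetic conditions do *not* emulate: real pangenome topologies
(bubble length distributions, shared haplotype structure), realistic score
autocorrelation along genomes, or graphs too wide for exact DP. Passing tests
therefore demonstrate algorithmic correctness on the covered graph classes,
not calibration on any particular biological dataset.

Problem sizes in the checks are chosen to exercise every code path while
keeping the exhaustive oracle exact: oracle comparisons use up to 7 vertices
and 10 edges (300 seeded instances across single-bag, path-cover and
TTSP-derived decompositions, four penalty values each), cross-solver
agreement uses sequences up to 50 vertices and TTSP graphs up to 40 leaf
edges, and the structural-constant checks use 100 TTSP graphs up to 50 leaf
edges and 50 random trees up to 30 vertices.

## Design choices made where the design was open

* **Undirected series-parallel graphs** get no dedicated module DP; the
  treewidth solver covers them through the same width-2 decomposition. A
  bespoke undirected TTSP recurrence would need to track whether terminals
  are path endpoints or interior points and whether both ends belong to one
  path; the general solver's configurations already encode all of that.
* **TTSP recognition** of arbitrary graphs is not implemented; TTSP structure
  arises constructively (EDS conversion, composition expressions, the
  generator). Linear-time recognition exists in the literature but is
  orthogonal to the scoring problem.
* **Which optimal path set is reported** is unspecified by the problem; any
  optimum is acceptable, the package fixes the deterministic tie-breaks above
  so repeated runs agree.
* **Empty input bags** in a user-supplied decomposition are contracted before
  rooting (a vertex's bags can never straddle an empty bag, so reconnecting
  its neighbours is safe).
* **Parallel duplicate edges** from TTSP composition collapse to one graph
  edge; edge multiplicity cannot change an optimum since a solution uses an
  edge at most once.

## Limitations

* Running time and table sizes grow superexponentially with the
  decomposition width; the solver is practical for the widths pangenome
  representations actually produce (2 for EDS-derived graphs, the number of
  covering sequences for alignment DAGs), not for arbitrary graphs.
* The package neither computes treewidth nor minimizes path covers; the
  decomposition is part of the input contract.
* Scores attach to vertices only; weighted edges, walks with repeated
  vertices (relevant for cyclic pangenomes with repeats) and per-haplotype
  diploid variants of the problem are out of scope.
* GFA ingestion of production pangenomes is not provided: mapping GFA
  segments to scored vertices requires a per-base splitting policy that is a
  modelling decision, not a file-format one.
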