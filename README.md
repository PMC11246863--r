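# msps — maximum-scoring path sets on pangenome graphs

Genomic segmentation asks for the high-scoring stretches of a score
sequence: assign every position a weight (log-odds of CpG membership,
ChIP-seq enrichment, mutation density, ...), charge a startup penalty *c*
per reported segment, and maximize the total of (segment weight sum − *c*)
over disjoint segments. `msps` generalizes this model from a single sequence
to a **vertex-weighted graph**, the setting of pangenomes, where one graph
represents many related genomes and each genome is a path. Given a directed
or undirected graph *G*, weights *w(v)* and a penalty *c ≥ 0*, a path
π = u₁…u_ℓ scores

&nbsp;&nbsp;&nbsp;&nbsp;*w*(π) = −*c* + Σⱼ *w*(uⱼ),

and the **maximum-scoring path sets** (MSPS) problem asks for vertex-disjoint
simple paths maximizing Σᵢ *w*(πᵢ). The problem is NP-hard in general (it
contains Hamiltonian path), so the package solves it exactly on the graph
classes pangenome representations actually produce:

* **sequences** (path graphs) — the classical two-state linear scan;
* **two-terminal series-parallel (TTSP) directed graphs** — a four-state DP
  over the binary decomposition tree, with direct conversion from **elastic
  degenerate strings** (`"A{C,G}T"`, nesting and empty alternatives
  supported);
* **any graph with a small-width tree decomposition** — a bottom-up
  configuration DP over a rooted binary decomposition, linear in the number
  of bags at fixed width, directed or undirected, cycles allowed. Width ≤ 2
  decompositions come for free from TTSP structure; a DAG covered by *k*
  paths (a pangenome built from *k* sequences) gets a width ≤ *k* path
  decomposition from the covering paths;
* an **exhaustive oracle** for small instances, against which everything is
  tested.

For the model, the recurrences, preprocessing, tie-breaking and the
configuration machinery, see the methods vignette
(`vignettes/msps-methods.Rmd`).

## Worked example

Segmenting a score sequence (weights 2, −1, −1, 3, 1, −4, 2 with penalty 1):

```r
library(msps)
solve_sequence(c(2, -1, -1, 3, 1, -4, 2), c = 1)
#> $score
#> [1] 5
#> $intervals
#>      start end
#> [1,]     0   1
#> [2,]     3   5
#> [3,]     6   7
```

Three segments — positions {1}, {4,5} and {7} in 1-based terms — for a total
of (2−1) + (3+1−1) + (2−1) = 5: positions 4 and 5 merge into one segment
(paying the penalty once), and neither −1 gap is worth bridging at *c* = 1.

The same model on a pangenome given as an elastic degenerate string, scoring
C/G positively (GC-rich region search across all represented haplotypes at
once):

```r
tg <- eds_to_ttsp("A{CG,T}A{C,}G", c(A = -1, C = 2, G = 2, T = -2))
res <- solve_msps(ttsp = tg, c = 1.5)
res$score
#> [1] 5.5
res$path_set
#> msps_path_set: 1 path(s), total score 5.5
#>   x0002.C -> x0003.G -> e0003 -> x0005.A -> e0004 -> x0006.C -> e0005 -> x0007.G
```

One path worth 2+2+0−1+0+2+0+2 − 1.5 = 5.5: it takes the CG alternative of
the first degenerate symbol, bridges the weight −1 A, and continues through
the C alternative to the final G (vertices `e...` are the weight-0 auxiliary
vertices flanking each symbol; `x<i>.<char>` are character positions). The
general treewidth solver run on the width-2 decomposition derived from the
same TTSP structure returns the identical optimum:

```r
td <- ttsp_to_tree_decomposition(tg)
td_width(td)
#> [1] 2
solve_treewidth(tg$graph, td, 1.5)$score
#> [1] 5.5
```

A command-line front end wrapping these functions ships as
`inst/scripts/msps.R` (subcommands `solve`, `from-eds`, `decompose-paths`,
`decompose-ttsp`, `validate`, `random`; PACE-style `.gr`/`.td` files with a
sidecar name table, TSV/JSON solution output).

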