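# Independent oracles used to double-check the package's solvers. These are
# deliberately naive and share no code with the implementations under test.

# all simple paths (as vertex sequences) of a small graph, including
# single-vertex paths; undirected paths are canonicalized (first <= last)
all_simple_paths <- function(graph) {
  vs <- sort(graph$vertices, method = "radix")
  em <- graph$edges
  succ <- function(v) {
    out <- em[em[, 1L] == v, 2L]
    if (!graph$directed) out <- c(out, em[em[, 2L] == v, 1L])
    out
  }
  res <- as.list(vs)
  extend <- function(p) {
    for (u in succ(p[length(p)])) {
      if (u %in% p) next
      p2 <- c(p, u)
      if (graph$directed || p2[1L] <= p2[length(p2)])
        res[[length(res) + 1L]] <<- p2
      extend(p2)
    }
  }
  for (v in vs) extend(v)
  if (!graph$directed) {
    keys <- vapply(res, paste, "", collapse = "\r")
    res <- res[!duplicated(keys)]
  }
  res
}

# exhaustive optimum by direct search over sets of vertex-disjoint simple
# paths (second, structurally different oracle)
pathset_oracle <- function(graph, c) {
  paths <- all_simple_paths(graph)
  scores <- vapply(paths, function(p) -c + sum(graph$weights[p]), numeric(1))
  keep <- scores > 0                   # zero/negative paths never improve
  paths <- paths[keep]; scores <- scores[keep]
  n <- length(paths)
  best <- 0
  rec <- function(i, used, acc) {
    if (i > n) { if (acc > best) best <<- acc; return(invisible()) }
    if (acc + sum(scores[i:n]) <= best) return(invisible())  # bound
    rec(i + 1L, used, acc)
    if (!any(paths[[i]] %in% used))
      rec(i + 1L, c(used, paths[[i]]), acc + scores[i])
    invisible()
  }
  if (n) rec(1L, character(0), 0)
  best
}

# Hamiltonian path existence by permutation enumeration
has_hamiltonian_path <- function(graph) {
  vs <- graph$vertices
  n <- length(vs)
  if (n <= 1L) return(TRUE)
  ok <- FALSE
  perm <- function(rest, acc) {
    if (ok) return(invisible())
    if (!length(rest)) { ok <<- TRUE; return(invisible()) }
    last <- if (length(acc)) acc[length(acc)] else NULL
    for (v in rest) {
      if (!is.null(last)) {
        em <- graph$edges
        hit <- if (graph$directed) any(em[, 1L] == last & em[, 2L] == v)
               else any((em[, 1L] == last & em[, 2L] == v) |
                        (em[, 2L] == last & em[, 1L] == v))
        if (!hit) next
      }
      perm(setdiff(rest, v), c(acc, v))
      if (ok) return(invisible())
    }
  }
  perm(vs, character(0))
  ok
}

# exhaustive maximum-scoring segment sets over all 2^n used-position masks
segment_oracle <- function(weights, c) {
  n <- length(weights)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    used <- bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L
    if (!any(used)) next
    r <- rle(used)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sc <- 0
    for (j in which(r$values))
      sc <- sc + sum(weights[starts[j]:ends[j]]) - c
    if (sc > best) best <- sc
  }
  best
}

# bag-per-edge path decomposition of a path graph (for cross-solver checks)
bag_per_edge_td <- function(graph) {
  m <- nrow(graph$edges)
  if (m == 0L) return(single_bag_td(graph))
  bags <- lapply(seq_len(m), function(i) graph$edges[i, ])
  te <- if (m > 1L) cbind(seq_len(m - 1L), 2:m) else NULL
  tree_decomposition(bags, te)
}

expect_empty_report <- function(report) {
  expect_identical(report, character(0))
}

scratch_dir <- function() {
  d <- tempfile("msps-test-")
  dir.create(d)
  d
}
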