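## Seeded synthetic-instance generators. Every generator is a pure function
## of its arguments: the RNG state is saved, seeded, and restored, so the
## same call always yields the same instance without disturbing the caller's
## random stream.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rand_weights <- function(vs, wmin, wmax) {
  stats::setNames(as.numeric(sample(seq(wmin, wmax), length(vs),
                                    replace = TRUE)), vs)
}

#' Generate a random MSPS instance
#'
#' Generator kinds:
#' \describe{
#'   \item{`path`}{a chain of `n` weighted vertices.}
#'   \item{`tree`}{a random tree on `n` vertices (uniform random attachment)
#'     with the bag-per-edge tree decomposition (`td`).}
#'   \item{`ttsp`}{a random two-terminal series-parallel directed graph built
#'     by uniformly choosing series or parallel composition down to
#'     `leaf_edges` single edges; returns the `msps_ttsp` object as `ttsp`.}
#'   \item{`dag_from_paths`}{mimics a pangenome DAG built from a multiple
#'     sequence alignment of `k` sequences: `k` increasing random vertex
#'     sequences over a shared ordered pool of `n` vertices are merged; the
#'     sequences are returned as `cover` and cover every edge and vertex.}
#'   \item{`generic`}{`n` vertices and `m` distinct random edges.}
#' }
#' Vertex weights are integers drawn uniformly from `wmin:wmax` (default
#' -3..3, a regime where optimal solutions mix positive islands and bridged
#' gaps for penalties of order 1).
#'
#' @param kind One of `"path"`, `"tree"`, `"ttsp"`, `"dag_from_paths"`,
#'   `"generic"`.
#' @param n Number of vertices (pool size for `dag_from_paths`).
#' @param m Number of edges (`generic` only).
#' @param k Number of covering sequences (`dag_from_paths` only).
#' @param leaf_edges Number of leaf edges (`ttsp` only).
#' @param wmin,wmax Integer weight range.
#' @param directed Logical (`tree` and `generic`; other kinds fix it).
#' @param seed Integer seed; fixes the instance completely.
#' @return A list with `graph` and, depending on kind, `td`, `ttsp`, or
#'   `cover`.
#' @export
generate_random_instance <- function(kind = c("path", "tree", "ttsp",
                                              "dag_from_paths", "generic"),
                                     n = 10L, m = NULL, k = 3L,
                                     leaf_edges = 10L,
                                     wmin = -3L, wmax = 3L,
                                     directed = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 1L, wmin <= wmax)
  with_local_seed(seed, switch(kind,
    path = {
      vs <- sprintf("v%04d", seq_len(n))
      g <- weighted_graph(vs, if (n > 1L) cbind(vs[-n], vs[-1L]),
                          rand_weights(vs, wmin, wmax), directed = directed)
      list(graph = g)
    },
    tree = {
      vs <- sprintf("v%04d", seq_len(n))
      em <- if (n > 1L) {
        parent <- vapply(2:n, function(i)
          if (i == 2L) 1L else sample.int(i - 1L, 1L), integer(1))
        cbind(vs[parent], vs[2:n])
      } else NULL
      g <- weighted_graph(vs, em, rand_weights(vs, wmin, wmax),
                          directed = directed)
      td <- if (n > 1L) {
        ## one bag per edge, bags adjacent when their edges share a vertex
        ## (chain the bags in the order the edges attach to the tree)
        bags <- lapply(seq_len(nrow(g$edges)),
                       function(i) g$edges[i, ])
        ## connect bag i to the earliest bag sharing a vertex
        te <- NULL
        for (i in seq_along(bags)[-1L]) {
          j <- which(vapply(bags[seq_len(i - 1L)],
                            function(b) length(intersect(b, bags[[i]])) > 0L,
                            logical(1)))[1L]
          if (is.na(j)) j <- i - 1L   # cannot happen in a tree
          te <- rbind(te, c(j, i))
        }
        tree_decomposition(bags, te)
      } else tree_decomposition(list(vs))
      list(graph = g, td = td)
    },
    ttsp = {
      stopifnot(leaf_edges >= 1L)
      env <- new.env(parent = emptyenv()); env$i <- 0L
      new_v <- function() { env$i <- env$i + 1L; sprintf("v%04d", env$i) }
      build <- function(e, s, t) {
        if (e == 1L) return(ttsp_edge(s, t))
        e1 <- sample.int(e - 1L, 1L)
        if (stats::runif(1) < 0.5) {
          mid <- new_v()
          ttsp_series(build(e1, s, mid), build(e - e1, mid, t))
        } else {
          ttsp_parallel(build(e1, s, t), build(e - e1, s, t))
        }
      }
      s <- new_v(); t <- new_v()
      root <- build(as.integer(leaf_edges), s, t)
      vs <- sort(unique(unlist(ttsp_edge_list(root))), method = "radix")
      tg <- ttsp_graph(root, rand_weights(vs, wmin, wmax))
      list(graph = tg$graph, ttsp = tg)
    },
    dag_from_paths = {
      stopifnot(k >= 1L, n >= 2L)
      pool <- sprintf("v%04d", seq_len(n))
      paths <- lapply(seq_len(k), function(i) {
        len <- sample(2:n, 1L)
        sort(sample(pool, len), method = "radix")
      })
      ## every pool vertex must be covered: insert strays into a random path
      stray <- setdiff(pool, unlist(paths))
      for (v in stray) {
        i <- sample.int(k, 1L)
        paths[[i]] <- sort(unique(c(paths[[i]], v)), method = "radix")
      }
      em <- unique(do.call(rbind, lapply(paths, function(p)
        if (length(p) > 1L) cbind(p[-length(p)], p[-1L]) else NULL)))
      vs <- sort(unique(unlist(paths)), method = "radix")
      g <- weighted_graph(vs, em, rand_weights(vs, wmin, wmax),
                          directed = TRUE)
      list(graph = g, cover = paths)
    },
    generic = {
      vs <- sprintf("v%04d", seq_len(n))
      all_pairs <- if (directed) {
        expand.grid(from = vs, to = vs, stringsAsFactors = FALSE)
      } else {
        idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
        data.frame(from = vs[idx[, 1L]], to = vs[idx[, 2L]],
                   stringsAsFactors = FALSE)
      }
      all_pairs <- all_pairs[all_pairs$from != all_pairs$to, , drop = FALSE]
      if (is.null(m)) m <- 2L * n
      m <- min(m, nrow(all_pairs))   # clamp to the available pairs
      em <- as.matrix(all_pairs[sample.int(nrow(all_pairs), m), , drop = FALSE])
      g <- weighted_graph(vs, if (m > 0L) em,
                          rand_weights(vs, wmin, wmax), directed = directed)
      list(graph = g)
    }
  ))
}
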