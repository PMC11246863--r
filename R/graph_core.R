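## Core graph and solution types for the MSPS problem.
##
## Vertices are opaque strings; all tie-breaking uses their radix sort order.
## Edges are stored as a two-column character matrix; in undirected graphs each
## edge is canonicalized so that the lexicographically smaller endpoint comes
## first. Self-loops and parallel edges are disallowed (they can never help an
## optimal path set).

#' Construct a vertex-weighted graph
#'
#' @param vertices Character vector of distinct vertex identifiers.
#' @param edges Two-column character matrix (or data frame) of edges; ordered
#'   pairs when `directed = TRUE`, unordered otherwise. `NULL` for no edges.
#' @param weights Numeric vertex weights; either a single value recycled to all
#'   vertices or a vector named by vertex (unnamed vectors must match
#'   `vertices` in length and order).
#' @param directed Logical; interpret edges as ordered pairs?
#'
#' @return An object of class `msps_graph`: a list with elements `directed`,
#'   `vertices`, `weights` (named numeric) and `edges` (two-column character
#'   matrix).
#' @examples
#' g <- weighted_graph(c("a", "b", "c"),
#'                     rbind(c("a", "b"), c("b", "c")),
#'                     weights = c(a = 5, b = -2, c = 3))
#' @export
weighted_graph <- function(vertices, edges = NULL, weights = 0, directed = TRUE) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) stop("duplicate vertex identifiers")
  if (length(weights) == 1L && is.null(names(weights))) {
    w <- rep(as.numeric(weights), length(vertices))
    names(w) <- vertices
  } else if (!is.null(names(weights))) {
    missing <- setdiff(vertices, names(weights))
    if (length(missing))
      stop("no weight for vertex: ", paste(missing, collapse = ", "))
    w <- as.numeric(weights[vertices])
    names(w) <- vertices
  } else {
    if (length(weights) != length(vertices))
      stop("weights must be named or match vertices in length")
    w <- as.numeric(weights)
    names(w) <- vertices
  }
  if (anyNA(w)) stop("vertex weights must be finite numbers")

  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stop("edges must have two columns")
    storage.mode(em) <- "character"
    unknown <- setdiff(c(em), vertices)
    if (length(unknown))
      stop("edge endpoint is not a declared vertex: ",
           paste(unknown, collapse = ", "))
    if (any(em[, 1L] == em[, 2L])) stop("self-loops are not allowed")
    if (!directed) {
      swap <- em[, 1L] > em[, 2L]
      em[swap, ] <- em[swap, c(2L, 1L), drop = FALSE]
    }
    em <- em[!duplicated(paste(em[, 1L], em[, 2L], sep = "\r")), , drop = FALSE]
  }
  dimnames(em) <- list(NULL, c("from", "to"))
  structure(list(directed = isTRUE(directed), vertices = vertices,
                 weights = w, edges = em),
            class = "msps_graph")
}

#' @export
print.msps_graph <- function(x, ...) {
  cat(sprintf("msps_graph: %d vertices, %d edges (%s)\n",
              length(x$vertices), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

## Number of vertices / edges
n_vertices <- function(graph) length(graph$vertices)
n_edges <- function(graph) nrow(graph$edges)

## Does the graph contain edge a->b (resp. {a,b})?
has_edge <- function(graph, a, b) {
  em <- graph$edges
  if (nrow(em) == 0L) return(FALSE)
  if (graph$directed) {
    any(em[, 1L] == a & em[, 2L] == b)
  } else {
    lo <- pmin(a, b); hi <- pmax(a, b)
    any(em[, 1L] == lo & em[, 2L] == hi)
  }
}

## Validity of a single path: character vector of problems (empty = valid).
path_problems <- function(path, graph) {
  path <- as.character(path)
  probs <- character(0)
  if (length(path) == 0L) return("path is empty")
  unknown <- setdiff(path, graph$vertices)
  if (length(unknown))
    probs <- c(probs, paste0("unknown vertex in path: ",
                             paste(unknown, collapse = ", ")))
  if (anyDuplicated(path))
    probs <- c(probs, paste0("repeated vertex in path: ",
                             paste(unique(path[duplicated(path)]),
                                   collapse = ", ")))
  if (length(path) > 1L && !length(probs)) {
    for (i in seq_len(length(path) - 1L)) {
      if (!has_edge(graph, path[i], path[i + 1L]))
        probs <- c(probs, sprintf("no edge from '%s' to '%s'",
                                  path[i], path[i + 1L]))
    }
  }
  probs
}

#' Score of a single path
#'
#' The score of a path with vertices `u_1, ..., u_l` is
#' `-c + sum(w(u_j))`: the startup penalty `c` is charged once per path.
#' A single vertex is a legal path of length zero.
#'
#' @param path Character vector of vertex identifiers, in path order.
#' @param graph An [weighted_graph()] object.
#' @param c Non-negative startup penalty.
#' @return The numeric path score.
#' @examples
#' g <- weighted_graph(c("a", "b"), rbind(c("a", "b")), c(a = 2, b = 3))
#' path_score(c("a", "b"), g, c = 1)  # 4
#' @export
path_score <- function(path, graph, c) {
  stopifnot(is.numeric(c), length(c) == 1L, c >= 0)
  probs <- path_problems(path, graph)
  if (length(probs)) stop("invalid path: ", paste(probs, collapse = "; "))
  -c + sum(graph$weights[as.character(path)])
}

#' Construct a path set (a candidate MSPS solution)
#'
#' A path set is a collection of paths together with its claimed total score.
#' Feasibility (pairwise vertex-disjointness, path validity) is checked by
#' [validate_path_set()], not by the constructor.
#'
#' @param paths List of character vectors (each a path).
#' @param total_score Claimed total score of the collection.
#' @return An object of class `msps_path_set`.
#' @export
path_set <- function(paths = list(), total_score = 0) {
  paths <- lapply(paths, as.character)
  structure(list(paths = paths, total_score = as.numeric(total_score)),
            class = "msps_path_set")
}

#' @export
print.msps_path_set <- function(x, ...) {
  cat(sprintf("msps_path_set: %d path(s), total score %g\n",
              length(x$paths), x$total_score))
  for (p in x$paths) cat("  ", paste(p, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

## Build a path set from explicit paths, computing the score.
path_set_from_paths <- function(paths, graph, c) {
  score <- sum(vapply(paths, path_score, numeric(1), graph = graph, c = c))
  if (length(paths) == 0L) score <- 0
  path_set(paths, score)
}

#' Validate a path set against a graph
#'
#' Checks that every path is a valid simple path of the graph, that paths are
#' pairwise vertex-disjoint, and that the stated total score matches the sum of
#' per-path scores under penalty `c`. The returned report is a character
#' vector of violations; a feasible, score-consistent path set yields an empty
#' report.
#'
#' @inheritParams path_score
#' @param ps An [path_set()] object.
#' @param tol Absolute tolerance for the score comparison.
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_path_set <- function(ps, graph, c, tol = 1e-9) {
  stopifnot(inherits(ps, "msps_path_set"))
  report <- character(0)
  for (i in seq_along(ps$paths)) {
    probs <- path_problems(ps$paths[[i]], graph)
    if (length(probs))
      report <- c(report, sprintf("path %d: %s", i,
                                  paste(probs, collapse = "; ")))
  }
  all_v <- unlist(ps$paths, use.names = FALSE)
  dup <- unique(all_v[duplicated(all_v)])
  if (length(dup))
    report <- c(report, paste0("vertex shared between paths: ",
                               paste(dup, collapse = ", ")))
  if (!length(report)) {
    true_score <- if (length(ps$paths)) {
      sum(vapply(ps$paths, path_score, numeric(1), graph = graph, c = c))
    } else 0
    if (abs(true_score - ps$total_score) > tol)
      report <- c(report, sprintf("score mismatch: stated %g, recomputed %g",
                                  ps$total_score, true_score))
  }
  report
}

#' Construct a solution edge set
#'
#' After preprocessing, a candidate solution is just a set of edges in which
#' every vertex is incident to at most one incoming and at most one outgoing
#' selected edge (directed), or to at most two selected edges (undirected);
#' its connected components are simple paths and cycles.
#'
#' @param edges Two-column character matrix of selected edges (may be empty).
#' @param graph The graph the edges come from.
#' @return An object of class `msps_edge_set`.
#' @export
solution_edge_set <- function(edges, graph) {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    storage.mode(em) <- "character"
    if (!graph$directed) {
      swap <- em[, 1L] > em[, 2L]
      em[swap, ] <- em[swap, c(2L, 1L), drop = FALSE]
    }
    em <- em[!duplicated(paste(em[, 1L], em[, 2L], sep = "\r")), , drop = FALSE]
    for (i in seq_len(nrow(em))) {
      if (!has_edge(graph, em[i, 1L], em[i, 2L]))
        stop(sprintf("selected edge (%s, %s) is not a graph edge",
                     em[i, 1L], em[i, 2L]))
    }
    if (graph$directed) {
      if (anyDuplicated(em[, 1L]) || anyDuplicated(em[, 2L]))
        stop("degree constraint violated: a vertex has two incoming or two outgoing selected edges")
    } else {
      deg <- table(c(em[, 1L], em[, 2L]))
      if (any(deg > 2L))
        stop("degree constraint violated: a vertex is incident to more than two selected edges")
    }
  }
  dimnames(em) <- list(NULL, c("from", "to"))
  structure(list(edges = em, directed = graph$directed),
            class = "msps_edge_set")
}

## Internal: order edges lexicographically by (from, to).
edge_order <- function(em) order(em[, 1L], em[, 2L], method = "radix")

#' Decompose a solution edge set into vertex-disjoint paths
#'
#' Connected components of a degree-constrained edge selection are simple
#' paths and cycles. Each cycle is opened into a path by dropping one edge
#' (the lexicographically smallest by `(from, to)`), which does not change the
#' score: the component keeps the same vertices and still counts as one path.
#'
#' @param sel An [solution_edge_set()] object.
#' @inheritParams path_score
#' @return An `msps_path_set` whose total score equals the score of `sel`
#'   (sum of covered vertex weights minus `c` per component).
#' @export
edges_to_path_set <- function(sel, graph, c) {
  stopifnot(inherits(sel, "msps_edge_set"))
  em <- sel$edges
  if (nrow(em) == 0L) return(path_set(list(), 0))
  em <- em[edge_order(em), , drop = FALSE]

  if (graph$directed) {
    nxt <- stats::setNames(em[, 2L], em[, 1L])
    verts <- unique(c(em))
    starts <- verts[!(verts %in% em[, 2L])]          # no incoming edge
    paths <- list()
    used <- character(0)
    for (s in sort(starts, method = "radix")) {
      p <- s
      while (p[length(p)] %in% names(nxt)) p <- c(p, nxt[[p[length(p)]]])
      paths[[length(paths) + 1L]] <- p
      used <- c(used, p)
    }
    ## remaining vertices lie on cycles; break each at its smallest edge
    remaining <- setdiff(verts, used)
    while (length(remaining)) {
      ## collect the cycle through the smallest remaining vertex
      v0 <- sort(remaining, method = "radix")[1L]
      cyc <- v0
      v <- nxt[[v0]]
      while (v != v0) { cyc <- c(cyc, v); v <- nxt[[v]] }
      ## cycle edges: (cyc_i, cyc_{i+1}); drop lexicographically smallest
      ce <- cbind(cyc, c(cyc[-1L], cyc[1L]))
      drop_i <- edge_order(ce)[1L]
      ## path starts at head of dropped edge's target
      start <- ce[drop_i, 2L]
      p <- start
      while (p[length(p)] != ce[drop_i, 1L]) p <- c(p, nxt[[p[length(p)]]])
      paths[[length(paths) + 1L]] <- p
      remaining <- setdiff(remaining, cyc)
    }
  } else {
    verts <- unique(c(em))
    adj <- lapply(stats::setNames(verts, verts), function(v) {
      c(em[em[, 1L] == v, 2L], em[em[, 2L] == v, 1L])
    })
    deg <- lengths(adj)
    paths <- list()
    visited <- character(0)
    walk_from <- function(s, first) {
      p <- c(s, first)
      repeat {
        v <- p[length(p)]; u <- p[length(p) - 1L]
        nbrs <- setdiff(adj[[v]], u)
        if (!length(nbrs) || nbrs[1L] %in% p) break
        p <- c(p, nbrs[1L])
      }
      p
    }
    ends <- sort(names(deg)[deg == 1L], method = "radix")
    for (s in ends) {
      if (s %in% visited) next
      p <- walk_from(s, adj[[s]][1L])
      paths[[length(paths) + 1L]] <- p
      visited <- c(visited, p)
    }
    remaining <- setdiff(verts, visited)
    while (length(remaining)) {      # cycles
      v0 <- sort(remaining, method = "radix")[1L]
      cyc <- v0
      prev <- NULL; v <- v0
      repeat {
        nbrs <- adj[[v]]
        nxt_v <- if (is.null(prev)) sort(nbrs, method = "radix")[1L] else setdiff(nbrs, prev)[1L]
        if (nxt_v == v0) break
        cyc <- c(cyc, nxt_v); prev <- v; v <- nxt_v
      }
      ce <- cbind(cyc, c(cyc[-1L], cyc[1L]))
      ces <- cbind(pmin(ce[, 1L], ce[, 2L]), pmax(ce[, 1L], ce[, 2L]))
      drop_i <- edge_order(ces)[1L]
      p <- c(ce[drop_i, 2L],
             if (drop_i < nrow(ce)) ce[(drop_i + 1L):nrow(ce), 2L],
             if (drop_i > 1L) ce[seq_len(drop_i - 1L), 2L])
      ## p now traverses the cycle starting after the dropped edge
      paths[[length(paths) + 1L]] <- p
      remaining <- setdiff(remaining, cyc)
    }
  }
  path_set_from_paths(paths, graph, c)
}

#' Exhaustive solver (test oracle) for small instances
#'
#' Enumerates every degree-feasible edge subset, scores it as the sum of
#' covered vertex weights minus `c` per connected component, and additionally
#' allows each uncovered vertex with `w(v) > c` to form a singleton path
#' (ties at `w(v) = c` are broken toward the smaller solution). Cycles in the
#' best selection are opened by [edges_to_path_set()] without changing the
#' score. Intended for graphs with at most `max_edges` edges.
#'
#' @inheritParams path_score
#' @param max_edges Size guard; instances with more edges are rejected.
#' @return A list with elements `score` (the optimum) and `path_set` (an
#'   optimal `msps_path_set`).
#' @export
solve_bruteforce <- function(graph, c, max_edges = 18L) {
  stopifnot(inherits(graph, "msps_graph"), is.numeric(c), c >= 0)
  m <- n_edges(graph)
  if (m > max_edges)
    stop(sprintf("instance too large for the exhaustive oracle (%d > %d edges)",
                 m, max_edges))
  vs <- sort(graph$vertices, method = "radix")
  w <- graph$weights[vs]
  em <- graph$edges
  if (m) em <- em[edge_order(em), , drop = FALSE]
  ei <- cbind(match(em[, 1L], vs), match(em[, 2L], vs))
  res <- cpp_bruteforce(length(vs), as.numeric(w), ei, graph$directed,
                        as.numeric(c))
  chosen <- em[res$edges, , drop = FALSE]
  ps <- edges_to_path_set(solution_edge_set(chosen, graph), graph, c)
  covered <- unlist(ps$paths, use.names = FALSE)
  singles <- vs[w > c & !(vs %in% covered)]
  if (length(singles)) {
    ps <- path_set(c(ps$paths, as.list(singles)),
                   ps$total_score + sum(w[singles] - c))
  }
  if (abs(ps$total_score - res$score) > 1e-9)
    stop("internal error: reconstructed path set does not attain the oracle score")
  list(score = res$score, path_set = ps)
}
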