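## Tree decompositions: data model, validation, the path-decomposition
## construction from an edge-covering path set of a DAG, and the
## preprocessing that turns a graph plus decomposition into the rooted binary
## form consumed by the treewidth solver.

#' Construct a tree decomposition
#'
#' @param bags List of character vectors; `bags[[i]]` is the vertex content of
#'   bag `i`.
#' @param edges Two-column integer matrix of tree edges between bag indices
#'   (`NULL` when there is a single bag).
#' @return An object of class `msps_td`.
#' @export
tree_decomposition <- function(bags, edges = NULL) {
  bags <- lapply(bags, function(b) sort(unique(as.character(b)), method = "radix"))
  if (!length(bags)) stop("a tree decomposition needs at least one bag")
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(integer(0), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    storage.mode(em) <- "integer"
    if (any(em < 1L | em > length(bags)))
      stop("tree edge references a nonexistent bag")
  }
  structure(list(bags = bags, edges = em), class = "msps_td")
}

#' @export
print.msps_td <- function(x, ...) {
  cat(sprintf("msps_td: %d bags, width %d\n", length(x$bags), td_width(x)))
  invisible(x)
}

#' Width of a tree decomposition
#'
#' The width is the maximum bag size minus one; the treewidth of a graph is
#' the minimum width over its tree decompositions.
#'
#' @param td An `msps_td` object.
#' @return Integer width.
#' @export
td_width <- function(td) {
  stopifnot(inherits(td, "msps_td"))
  if (!length(td$bags)) stop("empty decomposition has no width")
  max(lengths(td$bags)) - 1L
}

## adjacency list of the bag tree
td_adjacency <- function(td) {
  nb <- length(td$bags)
  adj <- vector("list", nb)
  for (i in seq_len(NROW(td$edges))) {
    a <- td$edges[i, 1L]; b <- td$edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Validate a tree decomposition against a graph
#'
#' Checks that the bag graph is a tree and the three defining conditions:
#' every vertex appears in some bag; every edge has both endpoints together in
#' some bag; and for every vertex, the bags containing it induce a connected
#' subtree.
#'
#' @param td An `msps_td` object.
#' @param graph An `msps_graph` object.
#' @return Character vector of violation messages (empty if valid).
#' @export
td_validate <- function(td, graph) {
  stopifnot(inherits(td, "msps_td"), inherits(graph, "msps_graph"))
  report <- character(0)
  nb <- length(td$bags)
  ne <- NROW(td$edges)
  if (ne != nb - 1L)
    report <- c(report, sprintf("bag graph is not a tree: %d bags need %d edges, got %d",
                                nb, nb - 1L, ne))
  adj <- td_adjacency(td)
  ## connectivity of the bag graph
  seen <- logical(nb)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    for (y in adj[[x]]) if (!seen[y]) { seen[y] <- TRUE; queue <- c(queue, y) }
  }
  if (!all(seen))
    report <- c(report, "bag graph is not connected")
  unknown <- setdiff(unique(unlist(td$bags)), graph$vertices)
  if (length(unknown))
    report <- c(report, paste0("bag contains unknown vertex: ",
                               paste(unknown, collapse = ", ")))
  ## condition 1
  missing_v <- setdiff(graph$vertices, unique(unlist(td$bags)))
  if (length(missing_v))
    report <- c(report, paste0("vertex in no bag: ",
                               paste(missing_v, collapse = ", ")))
  ## condition 2
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges[i, 1L]; b <- graph$edges[i, 2L]
    ok <- any(vapply(td$bags, function(bg) a %in% bg && b %in% bg, logical(1)))
    if (!ok)
      report <- c(report, sprintf("no bag contains both endpoints of edge (%s, %s)", a, b))
  }
  ## condition 3: bags containing v induce a connected subgraph of the tree
  if (all(seen) && ne == nb - 1L) {
    for (v in graph$vertices) {
      withv <- which(vapply(td$bags, function(bg) v %in% bg, logical(1)))
      if (length(withv) <= 1L) next
      seenv <- logical(nb)
      q <- withv[1L]; seenv[q] <- TRUE
      while (length(q)) {
        x <- q[1L]; q <- q[-1L]
        for (y in adj[[x]]) {
          if (!seenv[y] && y %in% withv) { seenv[y] <- TRUE; q <- c(q, y) }
        }
      }
      if (!all(seenv[withv]))
        report <- c(report, sprintf("bags containing vertex '%s' are not connected in the tree", v))
    }
  }
  report
}

#' Path decomposition of a DAG from an edge-covering path set
#'
#' Given a DAG and `k` paths that together cover every edge (and every
#' vertex), builds a path decomposition of width at most `k`: in a fixed
#' topological order `v_1, ..., v_n`, bag `X_i` contains `v_i` plus, for each
#' covering path, the most recent of `v_1, ..., v_{i-1}` on that path; bags
#' are chained in topological order. The topological order is computed with
#' lexicographic tie-breaking so the construction is reproducible.
#'
#' @param graph A directed acyclic `msps_graph`.
#' @param paths List of character vectors, each a path of `graph`; together
#'   they must cover all edges and vertices.
#' @return An `msps_td` path decomposition with one bag per vertex, in
#'   topological order.
#' @export
from_path_cover <- function(graph, paths) {
  stopifnot(inherits(graph, "msps_graph"))
  if (!graph$directed) stop("path-cover decomposition requires a directed graph")
  paths <- lapply(paths, as.character)
  for (i in seq_along(paths)) {
    probs <- path_problems(paths[[i]], graph)
    if (length(probs))
      stop(sprintf("cover path %d is not a valid path: %s", i,
                   paste(probs, collapse = "; ")))
  }
  ## coverage
  cov_v <- unique(unlist(paths))
  if (length(setdiff(graph$vertices, cov_v)))
    stop("cover paths miss vertices: ",
         paste(setdiff(graph$vertices, cov_v), collapse = ", "))
  edge_key <- function(em) paste(em[, 1L], em[, 2L], sep = "\r")
  pe <- unlist(lapply(paths, function(p) {
    if (length(p) > 1L) paste(p[-length(p)], p[-1L], sep = "\r") else character(0)
  }))
  missed <- setdiff(edge_key(graph$edges), pe)
  if (length(missed))
    stop("cover paths miss ", length(missed), " edge(s)")

  ## Kahn topological order with lexicographic tie-breaking
  vs <- graph$vertices
  indeg <- stats::setNames(integer(length(vs)), vs)
  for (i in seq_len(nrow(graph$edges)))
    indeg[graph$edges[i, 2L]] <- indeg[graph$edges[i, 2L]] + 1L
  succ <- split(graph$edges[, 2L], factor(graph$edges[, 1L], levels = vs))
  avail <- sort(names(indeg)[indeg == 0L], method = "radix")
  topo <- character(0)
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    topo <- c(topo, v)
    for (u in succ[[v]]) {
      indeg[u] <- indeg[u] - 1L
      if (indeg[u] == 0L) avail <- sort(c(avail, u), method = "radix")
    }
  }
  if (length(topo) != length(vs)) stop("graph contains a cycle")

  rank <- stats::setNames(seq_along(topo), topo)
  bags <- vector("list", length(topo))
  for (i in seq_along(topo)) {
    v <- topo[i]
    bag <- v
    for (p in paths) {
      before <- p[rank[p] < i]
      if (length(before)) bag <- c(bag, before[which.max(rank[before])])
    }
    bags[[i]] <- unique(bag)
  }
  edges <- if (length(bags) > 1L)
    cbind(seq_len(length(bags) - 1L), 2:length(bags)) else NULL
  tree_decomposition(bags, edges)
}

#' Trivial single-bag tree decomposition
#'
#' One bag containing every vertex; width `n - 1`. Useful for exercising the
#' treewidth solver on small instances without any structural decomposition.
#'
#' @param graph An `msps_graph` object.
#' @return An `msps_td` with one bag.
#' @export
single_bag_td <- function(graph) {
  tree_decomposition(list(graph$vertices))
}

## ---------------------------------------------------------------------------
## Preprocessing for the treewidth solver

aux_vertex_name <- function(v, taken) {
  nm <- paste0(v, "'")
  while (nm %in% taken) nm <- paste0(nm, "'")
  nm
}

#' Preprocess a graph and tree decomposition for the treewidth solver
#'
#' Performs the reductions that let a solution be represented as a pure edge
#' set with cycles allowed:
#' \enumerate{
#'   \item for every vertex `v` with `w(v) >= c`, adds an auxiliary vertex
#'     `v'` of weight 0, the edge `(v, v')` and a new leaf bag `{v, v'}`
#'     attached to the bag containing `v` closest to the root (this restores
#'     single-vertex paths, which the edge-set formulation would otherwise
#'     forbid);
#'   \item roots the tree at bag 1 and replaces any bag with more than two
#'     children by a left-leaning chain of duplicate bags;
#'   \item appends empty leaf bags so every nonempty bag has exactly two
#'     children;
#'   \item assigns every edge to the unique bag containing both endpoints that
#'     is closest to the root;
#'   \item computes each bag's terminals `X` intersect `parent(X)` (empty at
#'     the root).
#' }
#'
#' @param graph An `msps_graph`.
#' @param td A valid `msps_td` for `graph`.
#' @param c Non-negative startup penalty.
#' @return A list with `graph` (the extended graph) and `rd`, an object of
#'   class `msps_rd` with fields `bags`, `parent`, `children`, `root`,
#'   `terminals`, `bag_edges` (row indices into `graph$edges`), and `aux_map`
#'   (named character: auxiliary vertex -> original vertex).
#' @export
preprocess <- function(graph, td, c) {
  stopifnot(inherits(graph, "msps_graph"), inherits(td, "msps_td"),
            is.numeric(c), c >= 0)
  rep0 <- td_validate(td, graph)
  if (length(rep0))
    stop("invalid tree decomposition: ", paste(rep0, collapse = "; "))

  bags <- td$bags
  tedges <- lapply(seq_len(NROW(td$edges)),
                   function(i) c(td$edges[i, 1L], td$edges[i, 2L]))

  ## contract empty input bags (they carry no information; a vertex's bags
  ## can never straddle an empty bag, so reattaching neighbours is safe)
  repeat {
    empty <- which(lengths(bags) == 0L)
    if (!length(empty) || length(bags) == 1L) break
    e <- empty[1L]
    nbrs <- unique(unlist(lapply(tedges, function(x)
      if (e %in% x) setdiff(x, e) else NULL)))
    tedges <- Filter(function(x) !(e %in% x), tedges)
    if (length(nbrs) > 1L)
      for (i in 2:length(nbrs)) tedges <- c(tedges, list(c(nbrs[1L], nbrs[i])))
    keep <- setdiff(seq_along(bags), e)
    remap <- match(seq_along(bags), keep)
    bags <- bags[keep]
    tedges <- lapply(tedges, function(x) remap[x])
  }
  n_orig_bags <- length(bags)

  ## root at bag 1; BFS for parent/depth
  nb <- length(bags)
  adj <- vector("list", nb)
  for (x in tedges) {
    adj[[x[1L]]] <- c(adj[[x[1L]]], x[2L])
    adj[[x[2L]]] <- c(adj[[x[2L]]], x[1L])
  }
  parent <- rep(NA_integer_, nb); depth <- rep(NA_integer_, nb)
  depth[1L] <- 0L
  queue <- 1L
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    for (y in adj[[x]]) if (is.na(depth[y])) {
      depth[y] <- depth[x] + 1L; parent[y] <- x; queue <- c(queue, y)
    }
  }

  ## auxiliary vertices for every v with w(v) >= c
  g_dir <- graph$directed
  verts <- graph$vertices
  weights <- graph$weights
  new_edges <- graph$edges
  aux_map <- character(0)
  children <- vector("list", nb)
  for (i in seq_len(nb)) children[[i]] <- integer(0)
  for (i in which(!is.na(parent)))
    children[[parent[i]]] <- c(children[[parent[i]]], i)

  eligible <- sort(verts[weights[verts] >= c], method = "radix")
  for (v in eligible) {
    vp <- aux_vertex_name(v, verts)
    verts <- c(verts, vp)
    weights[vp] <- 0
    new_edges <- rbind(new_edges, c(v, vp))
    aux_map[vp] <- v
    holders <- which(vapply(bags, function(b) v %in% b, logical(1)))
    att <- holders[which.min(depth[holders])]
    bid <- length(bags) + 1L
    bags[[bid]] <- sort(c(v, vp), method = "radix")
    parent[bid] <- att; depth[bid] <- depth[att] + 1L
    children[[att]] <- c(children[[att]], bid)
    children[[bid]] <- integer(0)
  }

  pre_graph <- weighted_graph(verts, new_edges, weights[verts], directed = g_dir)

  ## binarize: replace a bag with > 2 children by a left-leaning chain of
  ## duplicates hosting the surplus children
  i <- 1L
  while (i <= length(bags)) {
    ch <- children[[i]]
    if (length(ch) > 2L) {
      dup <- length(bags) + 1L
      bags[[dup]] <- bags[[i]]
      parent[dup] <- i; depth[dup] <- depth[i] + 1L
      ## duplicate keeps all but the first child; original keeps first + dup
      moved <- ch[-1L]
      children[[dup]] <- moved
      for (mcd in moved) parent[mcd] <- dup
      children[[i]] <- c(ch[1L], dup)
      ## fix depths of the moved subtrees lazily (recomputed below)
    }
    i <- i + 1L
  }
  ## recompute depths (chain insertion shifted subtrees)
  nb <- length(bags)
  depth <- rep(NA_integer_, nb); depth[1L] <- 0L
  queue <- 1L
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    for (y in children[[x]]) { depth[y] <- depth[x] + 1L; queue <- c(queue, y) }
  }

  ## every nonempty bag gets exactly two children (append empty leaves)
  for (i in seq_len(nb)) {
    if (!length(bags[[i]])) next
    while (length(children[[i]]) < 2L) {
      bid <- length(bags) + 1L
      bags[[bid]] <- character(0)
      parent[bid] <- i; depth[bid] <- depth[i] + 1L
      children[[bid]] <- integer(0)
      children[[i]] <- c(children[[i]], bid)
    }
  }
  nb <- length(bags)

  ## assign each edge to the bag containing both endpoints closest to the root
  bag_edges <- vector("list", nb)
  for (i in seq_len(nb)) bag_edges[[i]] <- integer(0)
  for (ei in seq_len(nrow(pre_graph$edges))) {
    a <- pre_graph$edges[ei, 1L]; b <- pre_graph$edges[ei, 2L]
    holders <- which(vapply(bags, function(bg) a %in% bg && b %in% bg, logical(1)))
    if (!length(holders))
      stop(sprintf("internal error: no bag for edge (%s, %s)", a, b))
    h <- holders[which.min(depth[holders])]
    bag_edges[[h]] <- c(bag_edges[[h]], ei)
  }

  terminals <- vector("list", nb)
  for (i in seq_len(nb)) {
    terminals[[i]] <- if (is.na(parent[i])) character(0)
                      else sort(intersect(bags[[i]], bags[[parent[i]]]),
                                method = "radix")
  }

  rd <- structure(list(bags = bags, parent = parent, children = children,
                       root = 1L, terminals = terminals,
                       bag_edges = bag_edges, aux_map = aux_map,
                       n_original_bags = n_orig_bags),
                  class = "msps_rd")
  list(graph = pre_graph, rd = rd)
}

#' @export
print.msps_rd <- function(x, ...) {
  cat(sprintf("msps_rd: %d bags (root %d), %d auxiliary vertices\n",
              length(x$bags), x$root, length(x$aux_map)))
  invisible(x)
}

#' Convert a preprocessed-graph edge selection back to a path set
#'
#' Drops auxiliary vertices: a selected edge `(v, v')` means the original
#' solution uses `v`; if no other selected edge covers `v`, it becomes a
#' singleton path. Remaining edges are decomposed into paths (cycles opened)
#' by [edges_to_path_set()] on the original graph.
#'
#' @param sel An `msps_edge_set` on the preprocessed graph.
#' @param rd The `msps_rd` from [preprocess()].
#' @param graph The original `msps_graph`.
#' @inheritParams path_score
#' @return An `msps_path_set` on the original graph.
#' @export
postprocess_solution <- function(sel, rd, graph, c) {
  stopifnot(inherits(sel, "msps_edge_set"), inherits(rd, "msps_rd"))
  em <- sel$edges
  aux <- names(rd$aux_map)
  is_aux_edge <- em[, 1L] %in% aux | em[, 2L] %in% aux
  aux_em <- em[is_aux_edge, , drop = FALSE]
  ## an auxiliary vertex has degree 1, so it can only appear opposite its twin
  bad <- aux_em[!(aux_em[, 1L] %in% graph$vertices & aux_em[, 2L] %in% aux) &
                !(aux_em[, 2L] %in% graph$vertices & aux_em[, 1L] %in% aux), ,
                drop = FALSE]
  if (nrow(bad))
    stop("auxiliary vertex with unexpected incident edge")
  core <- em[!is_aux_edge, , drop = FALSE]
  ps <- if (nrow(core))
    edges_to_path_set(solution_edge_set(core, graph), graph, c)
  else path_set(list(), 0)
  covered <- unlist(ps$paths, use.names = FALSE)
  flagged <- unique(ifelse(aux_em[, 1L] %in% aux,
                           aux_em[, 2L], aux_em[, 1L]))
  singles <- sort(setdiff(flagged, covered), method = "radix")
  if (length(singles))
    ps <- path_set(c(ps$paths, as.list(singles)),
                   ps$total_score + sum(graph$weights[singles] - c))
  ps
}
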