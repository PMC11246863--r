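## The configuration DP over a rooted binary tree decomposition.
##
## The solver itself runs in compiled code (src/msps.cpp) and enumerates only
## extended configurations with a finite score: every such configuration is
## the combination of a reachable configuration of each child plus a
## degree-feasible subset of the bag's own edges. The functions in this file
## provide the same machinery on explicit R objects — candidate enumeration,
## validity, reduction to the parent configuration, child projections, the
## penalty and weight corrections — both as documentation of the algorithm
## and as an independently testable reference.
##
## Representation. For a bag X (sorted vertex names) an *extended
## configuration* is a pair of 2 x |X| character matrices `origin` and
## `target`. Rows are the two edge slots of each vertex ("in"/"out" for
## directed graphs, "slot1"/"slot2" for undirected ones); columns are the bag
## vertices. `origin` is one of "unused", "left", "right", "bag"; `target` is
## the next bag vertex along the path through that slot, the marker "NONE"
## when no bag vertex follows, or NA for unused slots. A *configuration*
## restricts to the bag's terminals and collapses origins to used/unused: a
## 2 x |T| target matrix (NA = unused).

#' Describe a bag for the configuration subroutines
#'
#' @param bag Character vector: the bag's vertices.
#' @param edges Two-column character matrix of the edges assigned to this bag
#'   (both endpoints must lie in `bag`), or `NULL`.
#' @param left,right Character vectors: the vertex contents of the two child
#'   bags (the bag's left/right terminal sets are their intersections with
#'   `bag`).
#' @param terminals Character vector: the bag's own terminals (intersection
#'   with its parent bag); empty at the root.
#' @param directed Logical.
#' @return An object of class `msps_bag_context`.
#' @export
bag_context <- function(bag, edges = NULL, left = character(0),
                        right = character(0), terminals = character(0),
                        directed = TRUE) {
  bag <- sort(unique(as.character(bag)), method = "radix")
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L)
  } else {
    em <- as.matrix(edges); storage.mode(em) <- "character"
    if (!all(c(em) %in% bag))
      stop("assigned edge endpoint outside the bag")
    if (!directed) {
      swap <- em[, 1L] > em[, 2L]
      em[swap, ] <- em[swap, c(2L, 1L), drop = FALSE]
    }
  }
  structure(list(bag = bag, edges = em,
                 t_left = sort(intersect(bag, left), method = "radix"),
                 t_right = sort(intersect(bag, right), method = "radix"),
                 terminals = sort(intersect(bag, terminals), method = "radix"),
                 directed = isTRUE(directed)),
            class = "msps_bag_context")
}

slot_names <- function(directed) if (directed) c("in", "out") else c("slot1", "slot2")

empty_ext_config <- function(ctx) {
  b <- length(ctx$bag)
  sn <- slot_names(ctx$directed)
  list(origin = matrix("unused", 2L, b, dimnames = list(sn, ctx$bag)),
       target = matrix(NA_character_, 2L, b, dimnames = list(sn, ctx$bag)))
}

## ---------------------------------------------------------------------------
## Enumeration

## all "linkages" through one subtree: assignments of the terminals' slots to
## that subtree with built-in reciprocity. Each linkage is a list of slot
## settings: list(vertex, slot, target) with slot 1 = in, 2 = out (directed).
subtree_linkages_directed <- function(Ts) {
  empty <- list(out = stats::setNames(rep(NA_character_, length(Ts)), Ts),
                `in` = stats::setNames(rep(NA_character_, length(Ts)), Ts),
                used_out = stats::setNames(rep(FALSE, length(Ts)), Ts),
                used_in = stats::setNames(rep(FALSE, length(Ts)), Ts))
  if (!length(Ts)) return(list(empty))
  ## assign out-slots in order; pairing claims the partner's in-slot
  assign_out <- function(link, i) {
    if (i > length(Ts)) return(finish_in(link, 1L))
    v <- Ts[i]
    out <- list()
    out <- c(out, assign_out(link, i + 1L))                 # out-slot unused
    l2 <- link; l2$out[v] <- "NONE"; l2$used_out[v] <- TRUE # dangles inside
    out <- c(out, assign_out(l2, i + 1L))
    for (u in Ts[!link$used_in]) {                          # reciprocal pair
      l2 <- link
      l2$out[v] <- u; l2$used_out[v] <- TRUE
      l2$`in`[u] <- v; l2$used_in[u] <- TRUE
      out <- c(out, assign_out(l2, i + 1L))
    }
    out
  }
  finish_in <- function(link, i) {
    if (i > length(Ts)) return(list(link))
    v <- Ts[i]
    if (link$used_in[v]) return(finish_in(link, i + 1L))
    out <- finish_in(link, i + 1L)                          # in-slot unused
    l2 <- link; l2$`in`[v] <- "NONE"; l2$used_in[v] <- TRUE
    c(out, finish_in(l2, i + 1L))
  }
  assign_out(empty, 1L)
}

## undirected: slots are symmetric; enumerate matchings over the 2|Ts| slots
subtree_linkages_undirected <- function(Ts) {
  slots <- if (length(Ts)) cbind(rep(Ts, each = 2L), rep(1:2, length(Ts))) else
    matrix(character(0), ncol = 2L)
  n <- NROW(slots)
  recs <- replicate(length(Ts), list(), simplify = FALSE)
  names(recs) <- Ts
  res <- list()
  rec <- function(state, i) {
    if (i > n) { res[[length(res) + 1L]] <<- state; return(invisible()) }
    if (state$done[i]) { rec(state, i + 1L); return(invisible()) }
    v <- slots[i, 1L]
    ## unused
    s2 <- state; s2$done[i] <- TRUE
    rec(s2, i + 1L)
    ## dangling into the subtree
    s2 <- state; s2$done[i] <- TRUE
    s2$recs[[v]] <- c(s2$recs[[v]], "NONE")
    rec(s2, i + 1L)
    ## paired with a later free slot (possibly of the same vertex: a loop
    ## path leaving and re-entering v through the subtree)
    later <- which(!state$done & seq_len(n) > i)
    for (j in later) {
      u <- slots[j, 1L]
      s2 <- state; s2$done[i] <- TRUE; s2$done[j] <- TRUE
      s2$recs[[v]] <- c(s2$recs[[v]], u)
      s2$recs[[u]] <- c(s2$recs[[u]], v)
      rec(s2, i + 1L)
    }
  }
  rec(list(done = rep(FALSE, n), recs = recs), 1L)
  res <- lapply(res, function(s) s$recs)
  ## distinct record multisets only (slot symmetry makes some states equal)
  keys <- vapply(res, function(r)
    paste(vapply(r, function(x) paste(sort(unlist(x)), collapse = ","), ""),
          collapse = ";"), "")
  res[!duplicated(keys)]
}

## degree-feasible subsets of the assigned edges
edge_subsets <- function(ctx) {
  m <- nrow(ctx$edges)
  subsets <- list(integer(0))
  if (!m) return(subsets)
  for (k in seq_len(2^m - 1L)) {
    idx <- which(bitwAnd(k, bitwShiftL(1L, 0:(m - 1L))) != 0L)
    em <- ctx$edges[idx, , drop = FALSE]
    ok <- if (ctx$directed) {
      !anyDuplicated(em[, 1L]) && !anyDuplicated(em[, 2L])
    } else {
      all(table(c(em)) <= 2L)
    }
    if (ok) subsets[[length(subsets) + 1L]] <- idx
  }
  subsets
}

#' Enumerate candidate extended configurations of a bag
#'
#' Builds every extended configuration that is valid by construction: a
#' choice of reciprocal subtree connections for the left and the right
#' terminal set, plus a degree-feasible subset of the bag's assigned edges,
#' subject to each slot being used at most once. The count never exceeds
#' `(3|X| + 4)^(2|X|)`. In undirected bags, configurations equal up to the
#' slot symmetry are returned once.
#'
#' @param ctx An [bag_context()] object.
#' @return List of extended configurations (each a list with matrices
#'   `origin` and `target`; see the file header for the representation).
#' @export
enumerate_extended_configs <- function(ctx) {
  stopifnot(inherits(ctx, "msps_bag_context"))
  subsets <- edge_subsets(ctx)
  out <- list()
  if (ctx$directed) {
    linkL <- subtree_linkages_directed(ctx$t_left)
    linkR <- subtree_linkages_directed(ctx$t_right)
    for (ll in linkL) for (lr in linkR) for (S in subsets) {
      E <- empty_ext_config(ctx)
      ok <- TRUE
      apply_link <- function(link, side) {
        for (v in names(link$out)) {
          if (!is.na(link$out[[v]])) {
            if (E$origin["out", v] != "unused") { ok <<- FALSE; return() }
            E$origin["out", v] <<- side; E$target["out", v] <<- link$out[[v]]
          }
          if (!is.na(link$`in`[[v]])) {
            if (E$origin["in", v] != "unused") { ok <<- FALSE; return() }
            E$origin["in", v] <<- side; E$target["in", v] <<- link$`in`[[v]]
          }
        }
      }
      apply_link(ll, "left"); if (!ok) next
      apply_link(lr, "right"); if (!ok) next
      for (ei in S) {
        a <- ctx$edges[ei, 1L]; b <- ctx$edges[ei, 2L]
        if (E$origin["out", a] != "unused" || E$origin["in", b] != "unused") {
          ok <- FALSE; break
        }
        E$origin["out", a] <- "bag"; E$target["out", a] <- b
        E$origin["in", b] <- "bag"; E$target["in", b] <- a
      }
      if (ok) out[[length(out) + 1L]] <- E
    }
  } else {
    linkL <- subtree_linkages_undirected(ctx$t_left)
    linkR <- subtree_linkages_undirected(ctx$t_right)
    for (ll in linkL) for (lr in linkR) for (S in subsets) {
      ## records per vertex: list of c(origin, target)
      recs <- lapply(stats::setNames(ctx$bag, ctx$bag), function(v) list())
      ok <- TRUE
      add_rec <- function(v, o, tgt) {
        if (length(recs[[v]]) >= 2L) { ok <<- FALSE; return() }
        recs[[v]][[length(recs[[v]]) + 1L]] <<- c(o, tgt)
      }
      for (v in names(ll)) for (tgt in ll[[v]]) { add_rec(v, "left", tgt); if (!ok) break }
      if (ok) for (v in names(lr)) for (tgt in lr[[v]]) { add_rec(v, "right", tgt); if (!ok) break }
      if (ok) for (ei in S) {
        add_rec(ctx$edges[ei, 1L], "bag", ctx$edges[ei, 2L]); if (!ok) break
        add_rec(ctx$edges[ei, 2L], "bag", ctx$edges[ei, 1L]); if (!ok) break
      }
      if (!ok) next
      E <- empty_ext_config(ctx)
      for (v in ctx$bag) {
        rr <- recs[[v]]
        if (!length(rr)) next
        ## canonical slot order: by target (NONE last), then origin
        tgt <- vapply(rr, function(r) r[2], "")
        org <- vapply(rr, function(r) r[1], "")
        rr <- rr[order(tgt == "NONE", tgt, org, method = "radix")]
        for (s in seq_along(rr)) {
          E$origin[s, v] <- rr[[s]][1]; E$target[s, v] <- rr[[s]][2]
        }
      }
      out[[length(out) + 1L]] <- E
    }
    keys <- vapply(out, function(E)
      paste(c(E$origin, E$target), collapse = "|"), "")
    out <- out[!duplicated(keys)]
  }
  out
}

## ---------------------------------------------------------------------------
## Validity

#' Check an extended configuration for internal consistency
#'
#' A valid extended configuration has reciprocal pointers: if a slot of `v`
#' points to `u` via some subtree, `u` must point back to `v` via the same
#' subtree and both must belong to that child's bag; pointers via the bag
#' itself must correspond to an edge assigned to the bag (with the right
#' orientation in directed graphs); mutual double pointers must pair up
#' consistently.
#'
#' @param E An extended configuration.
#' @param ctx An [bag_context()] object.
#' @return `TRUE` or `FALSE`.
#' @export
ec_is_valid <- function(E, ctx) {
  stopifnot(inherits(ctx, "msps_bag_context"))
  side_set <- list(left = ctx$t_left, right = ctx$t_right)
  has_assigned_edge <- function(a, b) {
    em <- ctx$edges
    if (!nrow(em)) return(FALSE)
    if (ctx$directed) any(em[, 1L] == a & em[, 2L] == b)
    else any(em[, 1L] == pmin(a, b) & em[, 2L] == pmax(a, b))
  }
  recs <- function(v) {
    r <- list()
    for (s in 1:2) if (E$origin[s, v] != "unused")
      r[[length(r) + 1L]] <- c(E$origin[s, v], E$target[s, v], s)
    r
  }
  for (v in ctx$bag) {
    for (s in 1:2) {
      o <- E$origin[s, v]; tgt <- E$target[s, v]
      if (o == "unused") {
        if (!is.na(tgt)) return(FALSE)
        next
      }
      if (is.na(tgt)) return(FALSE)
      if (o %in% c("left", "right")) {
        if (!(v %in% side_set[[o]])) return(FALSE)
        if (tgt != "NONE" && !(tgt %in% side_set[[o]])) return(FALSE)
      } else {                         # bag
        if (tgt == "NONE") return(FALSE)
        if (ctx$directed) {
          a <- if (s == 2L) v else tgt   # out slot: edge v->tgt; in: tgt->v
          b <- if (s == 2L) tgt else v
          if (!has_assigned_edge(a, b)) return(FALSE)
        } else {
          if (!has_assigned_edge(v, tgt)) return(FALSE)
        }
      }
      ## reciprocity
      if (tgt != "NONE") {
        if (ctx$directed) {
          s_back <- if (s == 1L) 2L else 1L    # in <-> out
          if (E$origin[s_back, tgt] != o || is.na(E$target[s_back, tgt]) ||
              E$target[s_back, tgt] != v) {
            ## a double pointer may use the mirror pairing; for the directed
            ## case slots are typed, so the reciprocal slot is fixed
            return(FALSE)
          }
        }
      }
    }
    if (!ctx$directed) {
      ## multiset reciprocity: v has as many (o, u) records as u has (o, v)
      for (r in recs(v)) {
        if (r[2] == "NONE") next
        cnt_vu <- sum(vapply(recs(v), function(x)
          x[1] == r[1] && x[2] == r[2], logical(1)))
        cnt_uv <- sum(vapply(recs(r[2]), function(x)
          x[1] == r[1] && x[2] == v, logical(1)))
        if (cnt_vu != cnt_uv) return(FALSE)
        if (r[1] == "bag" && cnt_vu > 1L) return(FALSE)  # would need parallel edges
      }
    }
  }
  TRUE
}

## ---------------------------------------------------------------------------
## Reduction and projections

## follow pointers from terminal v's slot until a terminal of `terms` is
## reached; returns the terminal, "NONE", or NA (slot unused)
chase_slot <- function(E, ctx, v, s) {
  if (E$origin[s, v] == "unused") return(NA_character_)
  terms <- ctx$terminals
  if (ctx$directed) {
    u <- E$target[s, v]
    steps <- 0L
    repeat {
      if (u == "NONE") return("NONE")
      if (u %in% terms) return(u)
      if ((steps <- steps + 1L) > length(ctx$bag) + 1L)
        stop("pointer chase did not terminate (invalid extended configuration)")
      if (E$origin[s, u] == "unused") return("NONE")
      u <- E$target[s, u]
    }
  } else {
    o <- E$origin[s, v]; u <- E$target[s, v]; prev <- v
    steps <- 0L
    repeat {
      if (u == "NONE") return("NONE")
      if (u %in% terms) return(u)
      if ((steps <- steps + 1L) > length(ctx$bag) + 1L)
        stop("pointer chase did not terminate (invalid extended configuration)")
      back <- which(E$origin[, u] != "unused" & E$target[, u] == prev &
                    E$origin[, u] == o)[1L]
      if (is.na(back))
        stop("reciprocal pointer missing (invalid extended configuration)")
      fwd <- if (back == 1L) 2L else 1L
      if (E$origin[fwd, u] == "unused") return("NONE")
      o <- E$origin[fwd, u]; prev <- u; u <- E$target[fwd, u]
    }
  }
}

#' Reduce an extended configuration to the bag's configuration
#'
#' Projects to the bag's terminals, collapsing each used slot's pointer to
#' the first *terminal* on its path by chasing pointers through non-terminal
#' bag vertices (resolving at each intermediate vertex which slot points back
#' and which points onward).
#'
#' @inheritParams ec_is_valid
#' @return A 2 x |terminals| character matrix of targets (`NA` = slot unused,
#'   `"NONE"` = used but no terminal reachable); undirected slot pairs are in
#'   canonical order.
#' @export
ec_reduce <- function(E, ctx) {
  terms <- ctx$terminals
  sn <- slot_names(ctx$directed)
  C <- matrix(NA_character_, 2L, length(terms), dimnames = list(sn, terms))
  for (v in terms) for (s in 1:2) C[s, v] <- chase_slot(E, ctx, v, s)
  if (!ctx$directed && length(terms)) {
    for (v in terms) {
      vals <- C[, v]
      is_none <- !is.na(vals) & vals == "NONE"
      C[, v] <- vals[order(is.na(vals), is_none,
                           ifelse(is.na(vals), "", vals), method = "radix")]
    }
  }
  C
}

#' Project an extended configuration onto one child's configuration
#'
#' For each terminal of the chosen child, a slot is used exactly when the
#' extended configuration marks its origin as that subtree, and the stored
#' pointer target carries over verbatim (the first bag vertex on the path is
#' also the first terminal of the child).
#'
#' @inheritParams ec_is_valid
#' @param side `"left"` or `"right"`.
#' @return A configuration matrix over the child's terminal set.
#' @export
ec_child_conf <- function(E, ctx, side = c("left", "right")) {
  side <- match.arg(side)
  terms <- if (side == "left") ctx$t_left else ctx$t_right
  sn <- slot_names(ctx$directed)
  C <- matrix(NA_character_, 2L, length(terms), dimnames = list(sn, terms))
  for (v in terms) {
    vals <- character(0)
    for (s in 1:2) {
      if (E$origin[s, v] == side) {
        if (ctx$directed) C[s, v] <- E$target[s, v]
        else vals <- c(vals, E$target[s, v])
      }
    }
    if (!ctx$directed && length(vals)) {
      vals <- vals[order(vals == "NONE", vals, method = "radix")]
      C[seq_along(vals), v] <- vals
    }
  }
  C
}

## connected components of the slot-pointer structure of a configuration
config_components_r <- function(C) {
  terms <- colnames(C)
  if (!length(terms)) return(0L)
  used <- apply(C, 2L, function(x) any(!is.na(x)))
  parent <- stats::setNames(terms, terms)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (v in terms) for (s in 1:2) {
    tgt <- C[s, v]
    if (!is.na(tgt) && tgt != "NONE")
      parent[[find(v)]] <- find(tgt)
  }
  length(unique(vapply(terms[used], find, "")))
}

#' Penalty correction when combining a bag's extended configuration
#'
#' Counts the connected components of the slot-pointer structure over the
#' bag's used vertices (each is one path or cycle touching the bag, so one
#' penalty `c` is due), subtracting `c` for each; then adds `c` back for
#' every component visible in each child's configuration, whose penalty the
#' child already paid. Components lying entirely inside a subtree never
#' surface here and keep the penalty paid below.
#'
#' @inheritParams ec_is_valid
#' @param C_left,C_right The children's configurations consistent with `E`
#'   (as returned by [ec_child_conf()]).
#' @param c Startup penalty.
#' @return The signed penalty correction (a multiple of `c`).
#' @export
ec_penalties <- function(E, C_left, C_right, ctx, c) {
  bag <- ctx$bag
  used <- vapply(bag, function(v) any(E$origin[, v] != "unused"), logical(1))
  parent <- stats::setNames(bag, bag)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (v in bag) for (s in 1:2) {
    tgt <- E$target[s, v]
    if (!is.na(tgt) && tgt != "NONE")
      parent[[find(v)]] <- find(tgt)
  }
  ncomp <- if (any(used)) length(unique(vapply(bag[used], find, ""))) else 0L
  -c * ncomp + c * config_components_r(C_left) + c * config_components_r(C_right)
}

#' Weight correction when combining a bag's extended configuration
#'
#' Adds the weight of every vertex used only by the bag's own edges (it
#' enters the solution here for the first time) and subtracts the weight of
#' every vertex used in both subtrees (both children counted it).
#'
#' @inheritParams ec_is_valid
#' @param weights Named numeric vector covering the bag's vertices.
#' @return The signed weight correction.
#' @export
ec_weight_delta <- function(E, ctx, weights) {
  delta <- 0
  for (v in ctx$bag) {
    o <- E$origin[, v]
    uL <- any(o == "left"); uR <- any(o == "right"); uB <- any(o == "bag")
    if (uB && !uL && !uR) delta <- delta + weights[[v]]
    if (uL && uR) delta <- delta - weights[[v]]
  }
  delta
}

## ---------------------------------------------------------------------------
## Solver pipeline

#' Solve MSPS over a tree decomposition
#'
#' Runs [preprocess()] and then the bottom-up configuration DP: leaves (empty
#' bags) hold a single empty configuration of score 0; an internal bag scores
#' every extended configuration as the two child configuration scores plus
#' the weight and penalty corrections, folding the result into the table
#' entry of its reduced configuration; the root's single empty configuration
#' holds the optimum. Configurations never reached are infeasible and simply
#' absent from the tables. The selected edges are recovered by traceback and
#' mapped back to a path set on the original graph.
#'
#' @param graph An `msps_graph`.
#' @param td A valid `msps_td` for `graph`; defaults to the single-bag
#'   decomposition for small graphs.
#' @param c Non-negative startup penalty.
#' @return A list with `score`, `path_set` (on the original graph),
#'   `edge_set` (the raw selection on the preprocessed graph) and
#'   `diagnostics` (per-bag size, terminal count, configuration-table size
#'   and number of extended configurations examined).
#' @export
solve_treewidth <- function(graph, td = NULL, c = 0) {
  stopifnot(inherits(graph, "msps_graph"))
  if (is.null(td)) {
    if (length(graph$vertices) > 12L)
      stop("no usable tree decomposition: supply 'td' for graphs this large")
    td <- single_bag_td(graph)
  }
  pp <- preprocess(graph, td, c)
  pg <- pp$graph; rd <- pp$rd
  vs <- pg$vertices
  vidx <- stats::setNames(seq_along(vs), vs)
  em <- pg$edges
  ei <- if (nrow(em)) cbind(vidx[em[, 1L]], vidx[em[, 2L]])
        else matrix(integer(0), ncol = 2L)
  storage.mode(ei) <- "integer"
  res <- cpp_solve_tw(length(vs), as.numeric(pg$weights[vs]), pg$directed,
                      ei,
                      lapply(rd$bags, function(b) unname(vidx[b])),
                      lapply(rd$children, as.integer),
                      rd$root,
                      lapply(rd$terminals, function(b) unname(vidx[b])),
                      lapply(rd$bag_edges, as.integer),
                      as.numeric(c))
  sel_rows <- em[res$edges, , drop = FALSE]
  sel <- solution_edge_set(sel_rows, pg)
  ps <- postprocess_solution(sel, rd, graph, c)
  if (abs(ps$total_score - res$score) > 1e-9)
    stop("internal error: traceback does not attain the DP optimum")
  list(score = res$score, path_set = ps, edge_set = sel,
       diagnostics = res$diagnostics)
}

## is `graph` a simple path? returns the vertex order or NULL
path_graph_order <- function(graph) {
  n <- length(graph$vertices)
  m <- nrow(graph$edges)
  if (n == 0L || m != n - 1L) return(NULL)
  if (n == 1L) return(graph$vertices)
  em <- graph$edges
  if (graph$directed) {
    if (anyDuplicated(em[, 1L]) || anyDuplicated(em[, 2L])) return(NULL)
    start <- setdiff(graph$vertices, em[, 2L])
    if (length(start) != 1L) return(NULL)
    nxt <- stats::setNames(em[, 2L], em[, 1L])
    ord <- start
    while (ord[length(ord)] %in% names(nxt))
      ord <- c(ord, nxt[[ord[length(ord)]]])
    if (length(ord) != n) return(NULL)
    ord
  } else {
    deg <- table(factor(c(em), levels = graph$vertices))
    if (any(deg > 2L) || sum(deg == 1L) != 2L) return(NULL)
    start <- sort(names(deg)[deg == 1L], method = "radix")[1L]
    adj <- lapply(stats::setNames(graph$vertices, graph$vertices), function(v)
      c(em[em[, 1L] == v, 2L], em[em[, 2L] == v, 1L]))
    ord <- start; prev <- NA_character_
    while (length(ord) < n) {
      nbrs <- setdiff(adj[[ord[length(ord)]]], prev)
      if (length(nbrs) != 1L) return(NULL)
      prev <- ord[length(ord)]
      ord <- c(ord, nbrs)
    }
    ord
  }
}

#' Solve the MSPS problem (dispatching front end)
#'
#' Picks a solver: the linear scan for path graphs, the module DP for TTSP
#' graphs, the treewidth DP when a tree decomposition or an edge-covering
#' path set is available, and the exhaustive oracle for tiny instances.
#'
#' @param graph An `msps_graph`; may be omitted when `ttsp` or `eds` is
#'   given.
#' @param c Non-negative startup penalty.
#' @param method One of `"auto"`, `"sequence"`, `"ttsp"`, `"treewidth"`,
#'   `"bruteforce"`.
#' @param td Optional `msps_td` tree decomposition.
#' @param cover Optional list of covering paths (see [from_path_cover()]).
#' @param ttsp Optional `msps_ttsp` object.
#' @param eds Optional elastic degenerate string (text or [parse_eds()]
#'   object); requires `char_weight`.
#' @param char_weight Named numeric character scores for `eds`.
#' @return A list with `score`, `path_set` and `method`.
#' @examples
#' g <- sequence_graph(c(5, -2, 3))
#' solve_msps(g, c = 1)$score   # 6
#' @export
solve_msps <- function(graph = NULL, c = 0,
                       method = c("auto", "sequence", "ttsp", "treewidth",
                                  "bruteforce"),
                       td = NULL, cover = NULL, ttsp = NULL, eds = NULL,
                       char_weight = NULL) {
  method <- match.arg(method)
  if (!is.null(eds)) {
    if (!is.null(ttsp)) stop("give either 'eds' or 'ttsp', not both")
    if (is.null(char_weight)) stop("'eds' requires 'char_weight'")
    ttsp <- eds_to_ttsp(eds, char_weight)
  }
  if (is.null(graph)) {
    if (is.null(ttsp)) stop("no input graph")
    graph <- ttsp$graph
  }
  if (length(graph$vertices) == 0L)
    return(list(score = 0, path_set = path_set(list(), 0), method = method))

  if (method == "auto") {
    method <- if (!is.null(ttsp)) "ttsp"
      else if (!is.null(path_graph_order(graph))) "sequence"
      else if (!is.null(td) || !is.null(cover)) "treewidth"
      else if (nrow(graph$edges) <= 18L) "bruteforce"
      else stop("no solver applicable: supply a decomposition or a path cover")
  }
  res <- switch(method,
    sequence = {
      ord <- path_graph_order(graph)
      if (is.null(ord)) stop("the sequence method requires a path graph")
      sol <- solve_sequence(graph$weights[ord], c)
      paths <- apply(sol$intervals, 1L, function(iv)
        ord[(iv[1L] + 1L):iv[2L]], simplify = FALSE)
      list(score = sol$score, path_set = path_set(paths, sol$score))
    },
    ttsp = {
      if (is.null(ttsp)) stop("the ttsp method requires a 'ttsp' (or 'eds') input")
      solve_ttsp(ttsp, c)
    },
    treewidth = {
      if (is.null(td)) {
        td <- if (!is.null(cover)) from_path_cover(graph, cover)
          else if (!is.null(ttsp)) ttsp_to_tree_decomposition(ttsp)
          else if (length(graph$vertices) <= 12L) single_bag_td(graph)
          else stop("no usable tree decomposition for the treewidth method")
      }
      r <- solve_treewidth(graph, td, c)
      list(score = r$score, path_set = r$path_set)
    },
    bruteforce = solve_bruteforce(graph, c)
  )
  list(score = res$score, path_set = res$path_set, method = method)
}
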