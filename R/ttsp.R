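## Two-terminal series-parallel (TTSP) directed graphs: binary decomposition
## trees, construction from elastic degenerate strings, and the four-state
## module DP.

## ---- decomposition tree nodes ---------------------------------------------

ttsp_node <- function(kind, s, t, left = NULL, right = NULL) {
  structure(list(kind = kind, s = s, t = t, left = left, right = right),
            class = "msps_ttsp_node")
}

#' TTSP building blocks
#'
#' A single edge `(s, t)` with `s != t` is a TTSP graph with terminals `s` and
#' `t`. Two TTSP graphs combine in series (the target of the first merges with
#' the source of the second) or in parallel (sources merge, targets merge).
#' These constructors build the binary decomposition tree; [ttsp_graph()]
#' turns a tree into a graph.
#'
#' @param s,t Source and target vertex identifiers.
#' @param left,right Child nodes (`msps_ttsp_node`).
#' @return An `msps_ttsp_node`.
#' @export
ttsp_edge <- function(s, t) {
  if (identical(s, t)) stop("TTSP edge must have distinct terminals")
  ttsp_node("edge", as.character(s), as.character(t))
}

#' @rdname ttsp_edge
#' @export
ttsp_series <- function(left, right) {
  stopifnot(inherits(left, "msps_ttsp_node"), inherits(right, "msps_ttsp_node"))
  if (!identical(left$t, right$s))
    stop("series composition requires left target to equal right source")
  if (identical(left$s, right$t))
    stop("series composition would merge source and target into one vertex")
  ttsp_node("series", left$s, right$t, left, right)
}

#' @rdname ttsp_edge
#' @export
ttsp_parallel <- function(left, right) {
  stopifnot(inherits(left, "msps_ttsp_node"), inherits(right, "msps_ttsp_node"))
  if (!identical(left$s, right$s) || !identical(left$t, right$t))
    stop("parallel composition requires both children to share terminals")
  ttsp_node("parallel", left$s, left$t, left, right)
}

## collect the edge list of a decomposition tree (with duplicates from
## parallel compositions)
ttsp_edge_list <- function(node) {
  if (node$kind == "edge") return(list(c(node$s, node$t)))
  c(ttsp_edge_list(node$left), ttsp_edge_list(node$right))
}

#' Assemble a TTSP graph from its decomposition tree
#'
#' Parallel compositions can create duplicate edges; these are collapsed to a
#' single edge in the graph (multiplicity never changes the optimum).
#'
#' @param root An `msps_ttsp_node` (from [ttsp_edge()] and friends or
#'   [eds_to_ttsp()]).
#' @param weights Named numeric vector of vertex weights (every vertex of the
#'   tree must be named), or a single value recycled.
#' @return An object of class `msps_ttsp`: list with `graph` (an
#'   `msps_graph`, directed) and `root` (the decomposition tree).
#' @export
ttsp_graph <- function(root, weights = 0) {
  stopifnot(inherits(root, "msps_ttsp_node"))
  el <- ttsp_edge_list(root)
  em <- do.call(rbind, el)
  vs <- sort(unique(c(em)), method = "radix")
  g <- weighted_graph(vs, em,
                      if (length(weights) == 1L && is.null(names(weights)))
                        weights else weights[vs],
                      directed = TRUE)
  structure(list(graph = g, root = root), class = "msps_ttsp")
}

#' @export
print.msps_ttsp <- function(x, ...) {
  cat(sprintf("msps_ttsp: %d vertices, %d edges, terminals %s -> %s\n",
              length(x$graph$vertices), nrow(x$graph$edges),
              x$root$s, x$root$t))
  invisible(x)
}

## ---- elastic degenerate strings -------------------------------------------

#' Parse an elastic degenerate string
#'
#' The accepted dialect: literal runs of characters outside braces; a
#' degenerate symbol is written `{alt1,alt2,...}` where each alternative is
#' itself an EDS (so nesting expresses generalized EDSs) and an empty
#' alternative denotes the empty string (`"{A,}"`). Whitespace is ignored.
#' Alternatives within one symbol must be distinct.
#'
#' @param text A single string.
#' @return An object of class `msps_eds`: a list of symbols; each symbol is
#'   either `list(kind = "literal", chars = "...")` or
#'   `list(kind = "degenerate", alts = list(<EDS symbol lists>))`.
#' @examples
#' parse_eds("A{C,G}T")
#' parse_eds("A{C{G,T},A}")   # nested (generalized) EDS
#' @export
parse_eds <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  chars <- chars[!grepl("\\s", chars)]
  pos <- 1L
  n <- length(chars)
  err <- function(msg, at = pos) stop(sprintf("EDS parse error at position %d: %s", at, msg))

  parse_symbols <- function(stop_chars) {
    symbols <- list()
    lit <- character(0)
    flush_lit <- function() {
      if (length(lit)) {
        symbols[[length(symbols) + 1L]] <<-
          list(kind = "literal", chars = paste(lit, collapse = ""))
        lit <<- character(0)
      }
    }
    while (pos <= n && !(chars[pos] %in% stop_chars)) {
      ch <- chars[pos]
      if (ch == "{") {
        flush_lit()
        open_at <- pos
        pos <<- pos + 1L
        alts <- list()
        repeat {
          alt <- parse_symbols(c(",", "}"))
          alts[[length(alts) + 1L]] <- alt
          if (pos > n) err("unbalanced '{'", open_at)
          if (chars[pos] == "}") { pos <<- pos + 1L; break }
          pos <<- pos + 1L    # consume ','
        }
        keys <- vapply(alts, function(a) paste(deparse(a), collapse = ""), "")
        if (anyDuplicated(keys)) err("duplicate alternatives in symbol", open_at)
        symbols[[length(symbols) + 1L]] <- list(kind = "degenerate", alts = alts)
      } else if (ch == "}" || ch == ",") {
        err(sprintf("unexpected '%s'", ch))
      } else if (grepl("^[A-Za-z0-9*#@._-]$", ch)) {
        lit <- c(lit, ch)
        pos <<- pos + 1L
      } else {
        err(sprintf("illegal character '%s'", ch))
      }
    }
    flush_lit()
    symbols
  }

  symbols <- parse_symbols(character(0))
  if (pos <= n) err(sprintf("unexpected '%s'", chars[pos]))
  if (!length(symbols)) stop("EDS must contain at least one symbol")
  structure(symbols, class = "msps_eds")
}

#' @export
print.msps_eds <- function(x, ...) {
  cat(sprintf("msps_eds: %d symbol(s)\n", length(x)))
  invisible(x)
}

#' Convert an elastic degenerate string to a TTSP graph
#'
#' One auxiliary vertex of weight 0 is placed before the first symbol, after
#' the last one, and between every pair of consecutive symbols; each
#' alternative of a degenerate symbol becomes a chain of one-character
#' vertices between the flanking auxiliary vertices, alternatives are composed
#' in parallel and symbols in series. An empty alternative contributes a
#' direct edge between the flanking auxiliary vertices, and nested symbols are
#' expanded recursively with the same flanking rule. The result is acyclic
#' with a single source and a single sink.
#'
#' Auxiliary vertices are named `e<i>`, character vertices `x<i>.<char>`.
#'
#' @param eds An [parse_eds()] object (or a string, parsed on the fly).
#' @param char_weight Named numeric vector mapping each character appearing in
#'   the EDS to its score.
#' @return An `msps_ttsp` object; the mapping from character vertices to
#'   characters is stored in attribute `labels` of the result.
#' @examples
#' eds_to_ttsp("{AC,G}", c(A = 1, C = 1, G = 1))
#' @export
eds_to_ttsp <- function(eds, char_weight) {
  if (is.character(eds)) eds <- parse_eds(eds)
  stopifnot(inherits(eds, "msps_eds"))
  env <- new.env(parent = emptyenv())
  env$naux <- 0L; env$nchar <- 0L
  env$weights <- numeric(0)
  env$labels <- character(0)
  new_aux <- function() {
    env$naux <- env$naux + 1L
    id <- sprintf("e%04d", env$naux)
    env$weights[id] <- 0
    id
  }
  new_char <- function(ch) {
    if (!ch %in% names(char_weight))
      stop(sprintf("no weight provided for character '%s'", ch))
    env$nchar <- env$nchar + 1L
    id <- sprintf("x%04d.%s", env$nchar, ch)
    env$weights[id] <- as.numeric(char_weight[[ch]])
    env$labels[id] <- ch
    id
  }
  chain <- function(ids) {            # series chain of edges over ids
    node <- ttsp_edge(ids[1L], ids[2L])
    for (i in seq_len(length(ids) - 2L))
      node <- ttsp_series(node, ttsp_edge(ids[i + 1L], ids[i + 2L]))
    node
  }
  build_symbol <- function(sym, a, b) {
    if (sym$kind == "literal") {
      ids <- c(a, vapply(strsplit(sym$chars, "")[[1]], new_char, ""), b)
      chain(ids)
    } else {
      node <- NULL
      for (alt in sym$alts) {
        alt_node <- if (length(alt) == 0L) ttsp_edge(a, b)
                    else build_symbols(alt, a, b)
        node <- if (is.null(node)) alt_node else ttsp_parallel(node, alt_node)
      }
      node
    }
  }
  build_symbols <- function(symbols, a, b) {
    m <- length(symbols)
    bounds <- c(a, if (m > 1L) vapply(seq_len(m - 1L), function(i) new_aux(), ""), b)
    node <- NULL
    for (i in seq_len(m)) {
      sn <- build_symbol(symbols[[i]], bounds[i], bounds[i + 1L])
      node <- if (is.null(node)) sn else ttsp_series(node, sn)
    }
    node
  }
  a0 <- new_aux()
  root <- build_symbols(unclass(eds), a0, new_aux())
  tg <- ttsp_graph(root, env$weights)
  attr(tg, "labels") <- env$labels
  tg
}

## ---- MSPS dynamic program on the decomposition tree ------------------------

#' Solve MSPS on a directed TTSP graph
#'
#' Bottom-up over the decomposition tree: for every module `H` with terminals
#' `s` and `t`, `M[H, u_s, u_t]` is the optimal score over path sets inside
#' `H` where `u_s` (`u_t`) says whether `s` (`t`) is used by a path. For a
#' single edge, `M = 0`, `w(s)-c`, `w(t)-c`, `w(s)+w(t)-c` for the four
#' states. A series composition merging `t_1 = s_2` either leaves the shared
#' vertex unused, or combines the two `t_1`-used subsolutions, subtracting the
#' double-counted `w(t_1)` and adding back the double-charged penalty `c`. A
#' parallel composition lets each terminal be used by at most one side.
#'
#' @param ttsp An `msps_ttsp` object (see [ttsp_graph()], [eds_to_ttsp()]).
#' @param c Non-negative startup penalty.
#' @return A list with `score` and `path_set` (an optimal `msps_path_set`).
#' @export
solve_ttsp <- function(ttsp, c) {
  stopifnot(inherits(ttsp, "msps_ttsp"), is.numeric(c), c >= 0)
  g <- ttsp$graph
  w <- g$weights

  ## returns list(M = numeric[4], pick): states ordered 00, 10, 01, 11
  ## pick[[state]] describes how to reconstruct (see rebuild below)
  dp <- function(node) {
    if (node$kind == "edge") {
      M <- c(0,
             w[[node$s]] - c,
             w[[node$t]] - c,
             w[[node$s]] + w[[node$t]] - c)
      return(list(node = node, M = M, left = NULL, right = NULL,
                  pick = NULL))
    }
    L <- dp(node$left); R <- dp(node$right)
    M <- numeric(4); pick <- vector("list", 4)
    st <- function(us, ut) 1L + us + 2L * ut
    if (node$kind == "series") {
      mid <- node$left$t
      for (us in 0:1) for (ut in 0:1) {
        cand <- c(L$M[st(us, 0)] + R$M[st(0, ut)],
                  L$M[st(us, 1)] + R$M[st(1, ut)] - w[[mid]] + c)
        k <- if (cand[1] >= cand[2]) 1L else 2L
        M[st(us, ut)] <- cand[k]
        pick[[st(us, ut)]] <- if (k == 1L) c(st(us, 0), st(0, ut))
                              else c(st(us, 1), st(1, ut))
      }
    } else {                       # parallel
      opts <- list(`1` = list(c(1L, 1L)),
                   `2` = list(c(2L, 1L), c(1L, 2L)),
                   `3` = list(c(3L, 1L), c(1L, 3L)),
                   `4` = list(c(4L, 1L), c(1L, 4L), c(2L, 3L), c(3L, 2L)))
      for (s4 in 1:4) {
        cand <- vapply(opts[[s4]], function(o) L$M[o[1]] + R$M[o[2]],
                       numeric(1))
        k <- which.max(cand)       # first maximum: deterministic
        M[s4] <- cand[k]
        pick[[s4]] <- opts[[s4]][[k]]
      }
    }
    list(node = node, M = M, left = L, right = R, pick = pick)
  }

  res <- dp(ttsp$root)
  best_state <- which.max(res$M)   # prefers fewer used terminals on ties
  score <- res$M[best_state]

  ## rebuild the used-edge set and singleton markers
  edges <- list(); singles <- character(0)
  rebuild <- function(r, state) {
    node <- r$node
    if (node$kind == "edge") {
      if (state == 4L) {
        edges[[length(edges) + 1L]] <<- c(node$s, node$t)
      } else if (state == 2L) {
        singles <<- c(singles, node$s)
      } else if (state == 3L) {
        singles <<- c(singles, node$t)
      }
      return(invisible())
    }
    p <- r$pick[[state]]
    rebuild(r$left, p[1]); rebuild(r$right, p[2])
  }
  rebuild(res, best_state)

  em <- if (length(edges)) do.call(rbind, edges) else NULL
  ps <- if (is.null(em)) path_set(list(), 0)
        else edges_to_path_set(solution_edge_set(em, g), g, c)
  covered <- unlist(ps$paths, use.names = FALSE)
  singles <- setdiff(unique(singles), covered)
  if (length(singles))
    ps <- path_set(c(ps$paths, as.list(sort(singles, method = "radix"))),
                   ps$total_score + sum(w[singles] - c))
  if (abs(ps$total_score - score) > 1e-9)
    stop("internal error: TTSP traceback does not attain the DP score")
  list(score = unname(score), path_set = ps)
}

#' Tree decomposition of a TTSP graph from its decomposition tree
#'
#' One bag per tree node: for an edge leaf the bag holds the edge's two
#' endpoints; for a parallel composition the two shared terminals; for a
#' series composition the outer terminals plus the merged middle vertex (bag
#' size 3). Decomposition-tree edges become tree edges of the result, so the
#' width is at most 2.
#'
#' @param ttsp An `msps_ttsp` object.
#' @return An `msps_td` tree decomposition (see [tree_decomposition()]); bag 1
#'   corresponds to the root module. Attribute `node_kind` records each bag's
#'   module type.
#' @export
ttsp_to_tree_decomposition <- function(ttsp) {
  stopifnot(inherits(ttsp, "msps_ttsp"))
  bags <- list(); kinds <- character(0); tedges <- list()
  walk <- function(node) {       # returns bag id, preorder
    id <- length(bags) + 1L
    bag <- switch(node$kind,
                  edge = c(node$s, node$t),
                  parallel = c(node$s, node$t),
                  series = c(node$s, node$left$t, node$t))
    bags[[id]] <<- sort(unique(bag), method = "radix")
    kinds[id] <<- node$kind
    if (node$kind != "edge") {
      lid <- walk(node$left)
      tedges[[length(tedges) + 1L]] <<- c(id, lid)
      rid <- walk(node$right)
      tedges[[length(tedges) + 1L]] <<- c(id, rid)
    }
    id
  }
  walk(ttsp$root)
  td <- tree_decomposition(bags,
                           if (length(tedges)) do.call(rbind, tedges) else NULL)
  attr(td, "node_kind") <- kinds
  td
}
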