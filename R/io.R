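## File formats: PACE-style .gr graphs and .td tree decompositions (with a
## sidecar name table for non-integer vertex identifiers), plain weight
## tables, path-cover files, EDS text files, and TSV/JSON solution output.

read_lines_nocomment <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "c ") & x != "c"]
}

#' Read / write a vertex-weighted graph in PACE-style format
#'
#' The graph file follows the PACE `.gr` dialect: an optional set of comment
#' lines starting with `c`, a header `p tw <n> <m>`, then one edge per line
#' (`<from> <to>`). Vertices are the integers `1..n`, used as string
#' identifiers. Weights live in a separate two-column table
#' (`<vertex> <weight>`, one per line); vertices missing from the table get
#' weight 0 with a warning. Duplicate edges are collapsed with a warning;
#' self-loops are an error.
#'
#' @param path Path of the `.gr` file.
#' @param weights_path Path of the weight table (`NULL` for all-zero weights).
#' @param directed Logical.
#' @return An `msps_graph`.
#' @export
read_graph <- function(path, weights_path = NULL, directed = TRUE) {
  ln <- read_lines_nocomment(path)
  if (!length(ln) || !grepl("^p\\s+tw\\s+\\d+\\s+\\d+$", ln[1L]))
    stop("malformed graph file: expected header 'p tw <n> <m>'")
  hd <- as.integer(strsplit(ln[1L], "\\s+")[[1]][3:4])
  n <- hd[1L]; m <- hd[2L]
  vs <- as.character(seq_len(n))
  el <- ln[-1L]
  if (length(el) != m)
    stop(sprintf("graph file declares %d edges but contains %d edge lines",
                 m, length(el)))
  em <- NULL
  if (length(el)) {
    parts <- strsplit(el, "\\s+")
    if (any(lengths(parts) != 2L)) stop("malformed edge line")
    em <- do.call(rbind, parts)
    bad <- setdiff(c(em), vs)
    if (length(bad))
      stop("edge references undeclared vertex: ", paste(bad, collapse = ", "))
    if (any(em[, 1L] == em[, 2L])) stop("self-loop in graph file")
    key <- if (directed) paste(em[, 1L], em[, 2L])
           else paste(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
    if (anyDuplicated(key)) {
      warning("duplicate edges collapsed")
      em <- em[!duplicated(key), , drop = FALSE]
    }
  }
  w <- stats::setNames(rep(0, n), vs)
  if (!is.null(weights_path)) {
    wl <- read_lines_nocomment(weights_path)
    parts <- strsplit(wl, "\\s+")
    if (any(lengths(parts) != 2L)) stop("malformed weight line")
    wt <- do.call(rbind, parts)
    unknown <- setdiff(wt[, 1L], vs)
    if (length(unknown))
      stop("weight table names unknown vertex: ", paste(unknown, collapse = ", "))
    w[wt[, 1L]] <- as.numeric(wt[, 2L])
    if (length(setdiff(vs, wt[, 1L])))
      warning("vertices missing from the weight table default to weight 0: ",
              paste(setdiff(vs, wt[, 1L]), collapse = ", "))
  }
  weighted_graph(vs, em, w, directed = directed)
}

#' @rdname read_graph
#' @param graph An `msps_graph` whose vertices are `1..n` (use
#'   [vertex_name_map()] to relabel first if needed).
#' @export
write_graph <- function(graph, path, weights_path = NULL) {
  vs <- graph$vertices
  if (!identical(sort(as.integer(vs)), seq_along(vs)))
    stop("write_graph requires vertices named 1..n; relabel first")
  em <- graph$edges
  lines <- c(sprintf("p tw %d %d", length(vs), nrow(em)),
             if (nrow(em)) paste(em[, 1L], em[, 2L]))
  writeLines(lines, path)
  if (!is.null(weights_path))
    writeLines(paste(vs, sprintf("%.17g", graph$weights[vs])),
               weights_path)
  invisible(path)
}

#' Relabel a graph's vertices to the integers 1..n
#'
#' @param graph An `msps_graph`.
#' @return A list with `graph` (relabelled) and `map` (named character,
#'   old name -> new integer label).
#' @export
vertex_name_map <- function(graph) {
  vs <- sort(graph$vertices, method = "radix")
  map <- stats::setNames(as.character(seq_along(vs)), vs)
  em <- graph$edges
  if (nrow(em)) em <- cbind(unname(map[em[, 1L]]), unname(map[em[, 2L]]))
  g2 <- weighted_graph(unname(map), em,
                       stats::setNames(as.numeric(graph$weights[vs]),
                                       unname(map)),
                       directed = graph$directed)
  list(graph = g2, map = map)
}

#' Read / write a tree decomposition in PACE .td format
#'
#' Format: comment lines `c ...`; a header `s td <#bags> <width+1> <#vertices>`;
#' one line `b <bag id> <vertex> <vertex> ...` per bag (possibly empty); then
#' one `<bag id> <bag id>` line per tree edge. A sidecar name map (as
#' produced by [vertex_name_map()]) translates integer labels back to vertex
#' names.
#'
#' @param path File path.
#' @param names Optional named character vector, vertex name -> integer label;
#'   when given, bag contents are translated back to names.
#' @return An `msps_td`.
#' @export
read_td <- function(path, names = NULL) {
  ln <- read_lines_nocomment(path)
  if (!length(ln) || !grepl("^s\\s+td\\s+\\d+\\s+\\d+\\s+\\d+$", ln[1L]))
    stop("malformed td file: expected header 's td <bags> <width+1> <n>'")
  nb <- as.integer(strsplit(ln[1L], "\\s+")[[1]][3L])
  body <- ln[-1L]
  bag_lines <- body[startsWith(body, "b ") | body == "b"]
  edge_lines <- setdiff(body, bag_lines)
  bags <- rep(list(character(0)), nb)
  for (bl in bag_lines) {
    parts <- strsplit(bl, "\\s+")[[1]][-1L]
    id <- as.integer(parts[1L])
    if (is.na(id) || id < 1L || id > nb) stop("bag id out of range in td file")
    content <- parts[-1L]
    if (!is.null(names)) {
      rev_map <- stats::setNames(names(names), names)
      unknown <- setdiff(content, names(rev_map))
      if (length(unknown))
        stop("td bag references unmapped vertex label: ",
             paste(unknown, collapse = ", "))
      content <- unname(rev_map[content])
    }
    bags[[id]] <- content
  }
  edges <- NULL
  if (length(edge_lines)) {
    parts <- strsplit(edge_lines, "\\s+")
    if (any(lengths(parts) != 2L)) stop("malformed tree edge line in td file")
    edges <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  }
  tree_decomposition(bags, edges)
}

#' @rdname read_td
#' @param td An `msps_td`.
#' @export
write_td <- function(td, path, names = NULL) {
  bags <- td$bags
  relabel <- function(b) {
    if (is.null(names)) b else unname(names[b])
  }
  all_v <- unique(unlist(bags))
  lines <- c(sprintf("s td %d %d %d", length(bags), max(lengths(bags)),
                     length(all_v)),
             vapply(seq_along(bags), function(i)
               trimws(paste("b", i, paste(relabel(bags[[i]]), collapse = " "))),
               ""),
             if (NROW(td$edges))
               paste(td$edges[, 1L], td$edges[, 2L]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a path-cover file
#'
#' One whitespace-separated vertex sequence per line.
#'
#' @param path File path.
#' @return List of character vectors.
#' @export
read_cover <- function(path) {
  ln <- read_lines_nocomment(path)
  lapply(strsplit(ln, "\\s+"), as.character)
}

#' Write / read a path-set solution
#'
#' TSV: a comment line `# total_score <score>`, a header
#' `path<TAB>score<TAB>vertices`, then one row per path with the vertex ids
#' joined by commas. JSON: `{score: ..., paths: [{vertices: [...], score:
#' ...}, ...]}`. Both round-trip losslessly.
#'
#' @param ps An `msps_path_set`.
#' @param path Output file.
#' @param graph The graph (to recompute per-path scores).
#' @param c Startup penalty used for per-path scores.
#' @param format `"tsv"` or `"json"`.
#' @export
write_solution <- function(ps, path, graph, c, format = c("tsv", "json")) {
  format <- match.arg(format)
  scores <- vapply(ps$paths, path_score, numeric(1), graph = graph, c = c)
  if (format == "tsv") {
    lines <- c(sprintf("# total_score %s",
                       sprintf("%.17g", ps$total_score)),
               "path\tscore\tvertices",
               if (length(ps$paths))
                 vapply(seq_along(ps$paths), function(i)
                   sprintf("%d\t%s\t%s", i,
                           sprintf("%.17g", scores[i]),
                           paste(ps$paths[[i]], collapse = ",")), ""))
    writeLines(lines, path)
  } else {
    obj <- list(score = ps$total_score,
                paths = lapply(seq_along(ps$paths), function(i)
                  list(vertices = ps$paths[[i]], score = scores[i])))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_solution
#' @export
read_solution <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ln <- readLines(path, warn = FALSE)
    total <- as.numeric(strsplit(ln[1L], "\\s+")[[1]][3L])
    body <- ln[-(1:2)]
    paths <- lapply(body, function(x)
      strsplit(strsplit(x, "\t")[[1]][3L], ",", fixed = TRUE)[[1]])
    path_set(paths, total)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    path_set(lapply(obj$paths, function(p) unlist(p$vertices)),
             as.numeric(obj$score))
  }
}
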