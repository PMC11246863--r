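## Maximum-scoring segment sets on a sequence of weights (MSPS on a path
## graph), by the classical two-state linear scan.

#' Maximum-scoring segment sets on a weight sequence
#'
#' Solves the MSPS problem when the graph is a simple path `v_1, ..., v_n`,
#' i.e. finds disjoint segments of the weight sequence maximizing the total of
#' (segment weight sum - `c`) over selected segments. Uses the two-state
#' recurrence
#' \deqn{M[i,0] = \max\{M[i-1,0], M[i-1,1]\}}
#' \deqn{M[i,1] = \max\{M[i-1,0] + w_i - c,\; M[i-1,1] + w_i\}}
#' with `M[1,0] = 0`, `M[1,1] = w_1 - c`, where state 1 means `v_i` is used by
#' a segment. A new segment is opened only when the previous vertex is unused:
#' two adjacent segments can always be merged, saving one penalty. The answer
#' is `max(M[n,0], M[n,1])`.
#'
#' Segments are reported as 0-based half-open index intervals (the recurrence
#' indices are 1-based; an interval `[a, b)` covers weights
#' `weights[(a+1):b]`). On ties the traceback prefers the vertex-unused state,
#' so the reported optimum covers as few vertices as possible among optima.
#'
#' @param weights Numeric vector of vertex weights (nonempty).
#' @param c Non-negative startup penalty per segment.
#' @return A list with `score` (the optimum) and `intervals`, an integer
#'   matrix with columns `start` and `end` (0-based half-open), rows in
#'   increasing order.
#' @examples
#' solve_sequence(c(5, -2, 3), c = 1)   # score 6, segments [0,1) and [2,3)
#' solve_sequence(c(5, -2, 3), c = 3)   # score 3, single segment [0,3)
#' @export
solve_sequence <- function(weights, c) {
  stopifnot(is.numeric(c), length(c) == 1L, c >= 0)
  weights <- as.numeric(weights)
  n <- length(weights)
  if (n == 0L) stop("'weights' must be nonempty")
  if (anyNA(weights)) stop("'weights' must be finite")

  M0 <- numeric(n); M1 <- numeric(n)
  ch0 <- integer(n); ch1 <- integer(n)   # predecessor state chosen (0 or 1)
  M0[1L] <- 0; M1[1L] <- weights[1L] - c
  if (n > 1L) {
    for (i in 2:n) {
      ## ties prefer the j = 0 predecessor
      if (M0[i - 1L] >= M1[i - 1L]) {
        M0[i] <- M0[i - 1L]; ch0[i] <- 0L
      } else {
        M0[i] <- M1[i - 1L]; ch0[i] <- 1L
      }
      start_new <- M0[i - 1L] + weights[i] - c
      extend <- M1[i - 1L] + weights[i]
      if (start_new >= extend) {
        M1[i] <- start_new; ch1[i] <- 0L
      } else {
        M1[i] <- extend; ch1[i] <- 1L
      }
    }
  }
  score <- max(M0[n], M1[n])
  state <- if (M0[n] >= M1[n]) 0L else 1L
  used <- logical(n)
  for (i in n:1) {
    used[i] <- state == 1L
    state <- if (i > 1L) (if (used[i]) ch1[i] else ch0[i]) else 0L
  }
  ## runs of used positions -> 0-based half-open intervals
  if (any(used)) {
    r <- rle(used)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    iv <- cbind(start = starts[r$values], end = ends[r$values])
  } else {
    iv <- cbind(start = integer(0), end = integer(0))
  }
  list(score = score, intervals = iv)
}

#' Build the path graph corresponding to a weight sequence
#'
#' Vertices are named `s0001, s0002, ...` in sequence order so that their
#' radix order matches the sequence order.
#'
#' @inheritParams solve_sequence
#' @param directed Orient edges along the sequence?
#' @return An [weighted_graph()] object.
#' @export
sequence_graph <- function(weights, directed = TRUE) {
  n <- length(weights)
  vs <- sprintf("s%04d", seq_len(n))
  edges <- if (n > 1L) cbind(vs[-n], vs[-1L]) else NULL
  weighted_graph(vs, edges, stats::setNames(as.numeric(weights), vs),
                 directed = directed)
}
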