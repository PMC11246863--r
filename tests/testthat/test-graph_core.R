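test_that("path scores follow -c + sum of vertex weights", {
  g <- weighted_graph(c("v1", "v2"), rbind(c("v1", "v2")), c(v1 = 2, v2 = 3))
  expect_equal(path_score(c("v1", "v2"), g, c = 1), 4)

  g1 <- weighted_graph("u", NULL, c(u = 5))
  expect_equal(path_score("u", g1, c = 2), 3)

  g2 <- weighted_graph(c("a", "b"), rbind(c("a", "b")), c(a = -1, b = -1))
  expect_equal(path_score(c("a", "b"), g2, c = 0), -2)

  ## invalid paths are rejected
  expect_error(path_score(c("b", "a"), g2, c = 0), "no edge")
  expect_error(path_score(c("a", "b", "a"), g2, c = 0), "repeated")
})

test_that("graph construction enforces the basic invariants", {
  expect_error(weighted_graph(c("a", "a")), "duplicate")
  expect_error(weighted_graph(c("a", "b"), rbind(c("a", "a"))), "self-loop")
  expect_error(weighted_graph(c("a"), rbind(c("a", "z"))), "not a declared vertex")
  ## duplicate edges collapse; undirected edges canonicalize
  g <- weighted_graph(c("a", "b"), rbind(c("b", "a"), c("a", "b")),
                      directed = FALSE)
  expect_equal(nrow(g$edges), 1L)
  expect_identical(unname(g$edges[1, ]), c("a", "b"))
})

test_that("validate_path_set reports disjointness, validity and score issues", {
  g <- weighted_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")),
                      c(a = 1, b = 1, c = 1))
  shared <- path_set(list(c("a", "b"), c("b", "c")), 0)
  rep1 <- validate_path_set(shared, g, c = 0)
  expect_true(any(grepl("shared", rep1)))
  expect_true(any(grepl("\\bb\\b", rep1)))

  expect_empty_report(validate_path_set(path_set(list(), 0), g, c = 1))

  off <- path_set(list(c("a", "b")), 2)   # true score is 1 at c = 1
  expect_true(any(grepl("score mismatch", validate_path_set(off, g, c = 1))))
})

test_that("edges_to_path_set decomposes selections and opens cycles", {
  g <- weighted_graph(c("a", "b", "c"),
                      rbind(c("a", "b"), c("b", "c"), c("c", "a")), 1)
  sel <- solution_edge_set(g$edges, g)
  ps <- edges_to_path_set(sel, g, c = 1)
  expect_length(ps$paths, 1L)
  expect_setequal(ps$paths[[1]], c("a", "b", "c"))
  expect_equal(ps$total_score, 2)        # cycle opened, score kept
  ## the dropped edge is the lexicographically smallest: (a,b); path b->c->a
  expect_identical(ps$paths[[1]], c("b", "c", "a"))

  expect_equal(edges_to_path_set(solution_edge_set(NULL, g), g, 1)$total_score, 0)

  g2 <- weighted_graph(c("a", "b", "x", "y"),
                       rbind(c("a", "b"), c("x", "y")), 1)
  ps2 <- edges_to_path_set(solution_edge_set(g2$edges, g2), g2, c = 0)
  expect_length(ps2$paths, 2L)
  expect_equal(ps2$total_score, 4)

  ## degree violations are refused
  g3 <- weighted_graph(c("a", "b", "c"), rbind(c("a", "b"), c("a", "c")), 1)
  expect_error(solution_edge_set(g3$edges, g3), "degree")
})

test_that("the exhaustive oracle matches its specification on small cases", {
  g <- weighted_graph(c("a", "b", "c"),
                      rbind(c("a", "b"), c("b", "c"), c("c", "a")), 1)
  r <- solve_bruteforce(g, c = 1)
  expect_equal(r$score, 2)
  expect_length(r$path_set$paths, 1L)

  g2 <- weighted_graph("v", NULL, c(v = 5))
  r2 <- solve_bruteforce(g2, c = 2)
  expect_equal(r2$score, 3)
  expect_identical(r2$path_set$paths, list("v"))

  g3 <- weighted_graph(c("a", "b"), rbind(c("a", "b")), c(a = -2, b = -1))
  expect_equal(solve_bruteforce(g3, c = 0)$score, 0)
  expect_length(solve_bruteforce(g3, c = 0)$path_set$paths, 0L)

  ## guard against oversized instances
  big <- generate_random_instance("generic", n = 8, m = 20, seed = 1)$graph
  expect_error(solve_bruteforce(big, 1), "too large")
})

test_that("double-entry verification: edge-subset oracle equals path-set oracle", {
  for (i in 1:25) {
    directed <- i %% 2 == 0
    n <- sample(2:6, 1)
    mcap <- if (directed) n * (n - 1) else n * (n - 1) / 2
    inst <- generate_random_instance("generic", n = n,
                                     m = sample(0:min(8L, mcap), 1),
                                     directed = directed, seed = 500 + i)
    for (c in c(0, 0.5, 1, 2)) {
      s1 <- solve_bruteforce(inst$graph, c)$score
      s2 <- pathset_oracle(inst$graph, c)
      expect_equal(s1, s2, info = sprintf("seed %d, c = %g", 500 + i, c))
    }
  }
})

test_that("closed forms and monotonicity of the optimum", {
  for (i in 1:10) {
    inst <- generate_random_instance("generic", n = sample(2:6, 1),
                                     m = sample(1:8, 1),
                                     directed = i %% 2 == 0, seed = 700 + i)
    g <- inst$graph
    pos <- sum(pmax(0, g$weights))
    ## c = 0: every positive vertex can be its own path
    expect_equal(solve_bruteforce(g, 0)$score, pos)
    ## c exceeding all positive weight: empty solution
    expect_equal(solve_bruteforce(g, pos + 1)$score, 0)
    ## monotone non-increasing in c
    cs <- c(0, 0.5, 1, 2, 4)
    scores <- vapply(cs, function(cc) solve_bruteforce(g, cc)$score, numeric(1))
    expect_true(all(diff(scores) <= 1e-12))
  }
})

test_that("optimum is non-decreasing under edge addition", {
  for (i in 1:8) {
    inst <- generate_random_instance("generic", n = 5, m = 8,
                                     directed = TRUE, seed = 900 + i)
    g <- inst$graph
    for (drop in sample(nrow(g$edges), 3)) {
      g2 <- weighted_graph(g$vertices, g$edges[-drop, , drop = FALSE],
                           g$weights, directed = TRUE)
      expect_lte(solve_bruteforce(g2, 1)$score, solve_bruteforce(g, 1)$score)
    }
  }
})

test_that("unit-weight score reaches n - c exactly when a Hamiltonian path exists", {
  for (i in 1:30) {
    n <- sample(3:6, 1)
    mcap <- n * (n - 1)
    inst <- generate_random_instance("generic", n = n,
                                     m = sample(2:min(9L, mcap), 1),
                                     directed = TRUE, seed = 1200 + i)
    g <- weighted_graph(inst$graph$vertices, inst$graph$edges, 1,
                        directed = TRUE)
    hits <- solve_bruteforce(g, 0.5)$score >= n - 0.5
    expect_identical(hits, has_hamiltonian_path(g),
                     info = sprintf("seed %d", 1200 + i))
  }
})
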