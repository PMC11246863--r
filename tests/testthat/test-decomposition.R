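test_that("decomposition validation checks the three defining conditions", {
  g <- weighted_graph(c("a", "b", "c", "d"),
                      rbind(c("a", "b"), c("b", "c"), c("c", "d")), 1)
  ## one bag with everything
  expect_empty_report(td_validate(single_bag_td(g), g))

  ## bag per edge, chained: valid, width 1
  td <- tree_decomposition(list(c("a", "b"), c("b", "c"), c("c", "d")),
                           rbind(c(1L, 2L), c(2L, 3L)))
  expect_empty_report(td_validate(td, g))
  expect_equal(td_width(td), 1L)

  ## deleting a bag orphans an edge (condition 2) and breaks the tree
  td2 <- tree_decomposition(list(c("a", "b"), c("c", "d")))
  rep2 <- td_validate(td2, g)
  expect_true(any(grepl("both endpoints.*\\(b, c\\)", rep2)))

  ## disconnected occurrence of a vertex (condition 3)
  td3 <- tree_decomposition(list(c("a", "b"), c("b", "c"), c("c", "d"),
                                 c("a", "d")),
                            rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)))
  rep3 <- td_validate(td3, g)
  expect_true(any(grepl("'a' are not connected", rep3)))
})

test_that("width is max bag size minus one", {
  expect_equal(td_width(tree_decomposition(list(c("a", "b"), c("b", "c")),
                                           rbind(c(1L, 2L)))), 1L)
  expect_equal(td_width(tree_decomposition(list(c("a", "b", "c", "d")))), 3L)
  expect_equal(td_width(tree_decomposition(list(c("a", "b"), c("a", "b", "c")),
                                           rbind(c(1L, 2L)))), 2L)
})

test_that("path-cover sweep reproduces the diamond worked example", {
  g <- weighted_graph(c("1", "2", "3", "4"),
                      rbind(c("1", "2"), c("2", "4"), c("1", "3"), c("3", "4")),
                      1)
  td <- from_path_cover(g, list(c("1", "2", "4"), c("1", "3", "4")))
  expect_equal(td$bags, list("1", c("1", "2"), c("1", "2", "3"),
                             c("2", "3", "4")))
  expect_equal(td_width(td), 2L)
  expect_empty_report(td_validate(td, g))
})

test_that("a path covered by itself yields the bag-per-step chain", {
  g <- sequence_graph(c(1, 2, 3, 4))
  ord <- sort(g$vertices, method = "radix")
  td <- from_path_cover(g, list(ord))
  expect_equal(lengths(td$bags), c(1L, 2L, 2L, 2L))
  expect_equal(td_width(td), 1L)
})

test_that("path-cover width is bounded by the number of covering paths", {
  for (i in 1:30) {
    k <- sample(2:4, 1)
    inst <- generate_random_instance("dag_from_paths", n = sample(4:12, 1),
                                     k = k, seed = 3100 + i)
    td <- from_path_cover(inst$graph, inst$cover)
    expect_empty_report(td_validate(td, inst$graph))
    expect_lte(td_width(td), k)
  }
})

test_that("path-cover construction rejects bad input", {
  g <- weighted_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")), 1)
  expect_error(from_path_cover(g, list(c("a", "b"))), "miss")
  gc <- weighted_graph(c("a", "b"), rbind(c("a", "b"), c("b", "a")), 1)
  expect_error(from_path_cover(gc, list(c("a", "b"), c("b", "a"))), "cycle")
  gu <- weighted_graph(c("a", "b"), rbind(c("a", "b")), 1, directed = FALSE)
  expect_error(from_path_cover(gu, list(c("a", "b"))), "directed")
})

test_that("preprocessing produces a well-formed rooted binary decomposition", {
  for (i in 1:12) {
    directed <- i %% 2 == 0
    inst <- generate_random_instance("generic", n = sample(2:7, 1),
                                     m = sample(1:9, 1),
                                     directed = directed, seed = 3300 + i)
    g <- inst$graph
    cc <- sample(c(0, 0.5, 1, 2), 1)
    pp <- preprocess(g, single_bag_td(g), cc)
    rd <- pp$rd; pg <- pp$graph

    ## every vertex with w >= c gained a weight-0 twin and a pendant edge
    eligible <- g$vertices[g$weights >= cc]
    expect_length(rd$aux_map, length(eligible))
    expect_setequal(unname(rd$aux_map), eligible)
    expect_true(all(pg$weights[names(rd$aux_map)] == 0))

    ## structural invariants
    for (b in seq_along(rd$bags)) {
      nch <- length(rd$children[[b]])
      if (length(rd$bags[[b]])) expect_equal(nch, 2L)
      if (nch == 0L) expect_length(rd$bags[[b]], 0L)
    }
    ## every edge assigned to exactly one bag that contains both endpoints
    assigned <- unlist(rd$bag_edges)
    expect_setequal(assigned, seq_len(nrow(pg$edges)))
    expect_length(assigned, nrow(pg$edges))
    for (b in seq_along(rd$bags)) {
      for (ei in rd$bag_edges[[b]]) {
        expect_true(all(pg$edges[ei, ] %in% rd$bags[[b]]))
      }
    }
    ## root has no terminals; terminals are bag-parent intersections
    expect_length(rd$terminals[[rd$root]], 0L)
    ## decomposition of the preprocessed graph is still valid
    nb <- length(rd$bags)
    te <- cbind(which(!is.na(rd$parent)), rd$parent[!is.na(rd$parent)])
    td2 <- tree_decomposition(rd$bags, te)
    expect_empty_report(td_validate(td2, pg))
    ## width can only grow to cover the pendant pairs
    expect_lte(td_width(td2), max(td_width(single_bag_td(g)), 1L))
    ## bag count stays linear
    expect_lte(nb, 4L * (rd$n_original_bags + length(rd$aux_map)) + 1L)
  }
})

test_that("bags with many children are binarized by duplication", {
  ## star decomposition: center bag with three children
  g <- weighted_graph(c("a", "b", "c", "d"),
                      rbind(c("a", "b"), c("a", "c"), c("a", "d")),
                      c(a = -5, b = -5, c = -5, d = -5))
  ## bag 1 becomes the root, so the big bag starts with three children
  td <- tree_decomposition(list(c("a", "b", "c", "d"), c("a", "b"),
                                c("a", "c"), c("a", "d")),
                           rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)))
  pp <- preprocess(g, td, 1)
  rd <- pp$rd
  expect_true(all(lengths(rd$children)[lengths(rd$bags) > 0] == 2L))
  ## duplicated copies of the big bag exist
  big <- vapply(rd$bags, function(b) length(b) == 4L, logical(1))
  expect_gte(sum(big), 2L)
  ## and the result still validates
  te <- cbind(which(!is.na(rd$parent)), rd$parent[!is.na(rd$parent)])
  expect_empty_report(td_validate(tree_decomposition(rd$bags, te), pp$graph))
})

test_that("postprocessing strips auxiliary vertices and restores singletons", {
  g <- weighted_graph(c("a", "b", "c"),
                      rbind(c("a", "b"), c("b", "c"), c("c", "a")),
                      c(a = 5, b = 1, c = 1))
  pp <- preprocess(g, single_bag_td(g), 2)
  pg <- pp$graph; rd <- pp$rd
  aux_a <- names(rd$aux_map)[rd$aux_map == "a"]

  ## a single auxiliary edge becomes the singleton path (v)
  sel <- solution_edge_set(rbind(c("a", aux_a)), pg)
  ps <- postprocess_solution(sel, rd, g, 2)
  expect_identical(ps$paths, list("a"))
  expect_equal(ps$total_score, 3)

  ## no auxiliary edges: identical to plain edge decomposition
  sel2 <- solution_edge_set(rbind(c("a", "b")), pg)
  ps2 <- postprocess_solution(sel2, rd, g, 2)
  expect_identical(ps2$paths,
                   edges_to_path_set(solution_edge_set(rbind(c("a", "b")), g),
                                     g, 2)$paths)

  ## a full cycle plus an auxiliary edge elsewhere is opened + singleton kept
  g2 <- weighted_graph(c("a", "b", "c", "z"),
                       rbind(c("a", "b"), c("b", "c"), c("c", "a")),
                       c(a = 1, b = 1, c = 1, z = 9))
  pp2 <- preprocess(g2, single_bag_td(g2), 1)
  aux_z <- names(pp2$rd$aux_map)[pp2$rd$aux_map == "z"]
  sel3 <- solution_edge_set(rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                                  c("z", aux_z)), pp2$graph)
  ps3 <- postprocess_solution(sel3, pp2$rd, g2, 1)
  expect_length(ps3$paths, 2L)
  expect_true(list("z") %in% ps3$paths || any(vapply(ps3$paths, identical,
                                                     logical(1), y = "z")))
  expect_equal(ps3$total_score, (3 - 1) + (9 - 1))
})

test_that("vertex occurrences stay connected after preprocessing", {
  for (i in 1:8) {
    inst <- generate_random_instance("ttsp", leaf_edges = sample(3:12, 1),
                                     seed = 3500 + i)
    td <- ttsp_to_tree_decomposition(inst$ttsp)
    pp <- preprocess(inst$graph, td, 1)
    rd <- pp$rd
    te <- cbind(which(!is.na(rd$parent)), rd$parent[!is.na(rd$parent)])
    expect_empty_report(td_validate(tree_decomposition(rd$bags, te), pp$graph))
  }
})
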