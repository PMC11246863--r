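# helpers to build explicit extended configurations in tests
ec_blank <- function(bag, directed = TRUE) {
  sn <- if (directed) c("in", "out") else c("slot1", "slot2")
  list(origin = matrix("unused", 2L, length(bag), dimnames = list(sn, bag)),
       target = matrix(NA_character_, 2L, length(bag),
                       dimnames = list(sn, bag)))
}
ec_set <- function(E, slot, v, origin, target) {
  E$origin[slot, v] <- origin
  E$target[slot, v] <- target
  E
}

test_that("candidate enumeration respects the extended-configuration bound", {
  ## empty bag: exactly one (empty) configuration
  ctx0 <- bag_context(character(0))
  expect_length(enumerate_extended_configs(ctx0), 1L)

  ## one vertex, directed: at most (3*1+4)^2 = 49 candidates
  ctx1 <- bag_context("a", left = "a", right = "a", terminals = "a")
  n1 <- length(enumerate_extended_configs(ctx1))
  expect_lte(n1, 49L)
  expect_gte(n1, 2L)

  for (i in 1:6) {
    set.seed(4000 + i)
    b <- sample(1:3, 1)
    bag <- letters[seq_len(b)]
    directed <- i %% 2 == 0
    edges <- if (b >= 2) rbind(bag[1:2]) else NULL
    ctx <- bag_context(bag, edges, left = sample(bag, sample(0:b, 1)),
                       right = sample(bag, sample(0:b, 1)),
                       terminals = sample(bag, sample(0:b, 1)),
                       directed = directed)
    cfgs <- enumerate_extended_configs(ctx)
    expect_lte(length(cfgs), (3 * b + 4)^(2 * b))
    expect_true(all(vapply(cfgs, ec_is_valid, logical(1), ctx = ctx)))
    keys <- vapply(cfgs, function(E) paste(c(E$origin, E$target), collapse = "|"), "")
    expect_false(anyDuplicated(keys) > 0)
  }
})

test_that("is_valid enforces reciprocity and edge existence", {
  ctx <- bag_context(c("u", "v"), rbind(c("u", "v")),
                     left = c("u", "v"), terminals = c("u", "v"))
  ## empty configuration is valid
  expect_true(ec_is_valid(ec_blank(c("u", "v")), ctx))

  ## v points to u via the left subtree but u's slots are unused
  E <- ec_set(ec_blank(c("u", "v")), "out", "v", "left", "u")
  expect_false(ec_is_valid(E, ctx))
  ## with the reciprocal pointer it becomes valid
  E <- ec_set(E, "in", "u", "left", "v")
  expect_true(ec_is_valid(E, ctx))

  ## pointing via the bag requires the assigned edge with that orientation
  E2 <- ec_set(ec_blank(c("u", "v")), "out", "u", "bag", "v")
  E2 <- ec_set(E2, "in", "v", "bag", "u")
  expect_true(ec_is_valid(E2, ctx))           # edge (u, v) is assigned
  E3 <- ec_set(ec_blank(c("u", "v")), "out", "v", "bag", "u")
  E3 <- ec_set(E3, "in", "u", "bag", "v")
  expect_false(ec_is_valid(E3, ctx))          # edge (v, u) is not

  ## subtree pointers require membership of that child's bag
  ctx2 <- bag_context(c("u", "v"), NULL, left = "u", terminals = c("u", "v"))
  E4 <- ec_set(ec_blank(c("u", "v")), "out", "v", "left", "NONE")
  expect_false(ec_is_valid(E4, ctx2))         # v is not in the left child
})

test_that("reduce_conf chases pointers through non-terminal vertices", {
  ## terminals a, b; m is internal: a -> m -> b realized in the left subtree
  ctx <- bag_context(c("a", "b", "m"), NULL, left = c("a", "b", "m"),
                     terminals = c("a", "b"))
  E <- ec_blank(c("a", "b", "m"))
  E <- ec_set(E, "out", "a", "left", "m")
  E <- ec_set(E, "in", "m", "left", "a")
  E <- ec_set(E, "out", "m", "left", "b")
  E <- ec_set(E, "in", "b", "left", "m")
  expect_true(ec_is_valid(E, ctx))
  C <- ec_reduce(E, ctx)
  expect_equal(unname(C["out", "a"]), "b")
  expect_equal(unname(C["in", "b"]), "a")
  expect_true(is.na(C["in", "a"]))

  ## all vertices terminal: targets copied unchanged
  ctx2 <- bag_context(c("a", "b"), NULL, left = c("a", "b"),
                      terminals = c("a", "b"))
  E2 <- ec_set(ec_blank(c("a", "b")), "out", "a", "left", "b")
  E2 <- ec_set(E2, "in", "b", "left", "a")
  C2 <- ec_reduce(E2, ctx2)
  expect_equal(unname(C2["out", "a"]), "b")

  ## NONE stays NONE
  E3 <- ec_set(ec_blank(c("a", "b")), "out", "a", "left", "NONE")
  expect_equal(unname(ec_reduce(E3, ctx2)["out", "a"]), "NONE")
})

test_that("child_conf projects exactly the slots of one subtree", {
  ctx <- bag_context(c("a", "b"), rbind(c("a", "b")),
                     left = c("a", "b"), right = c("a", "b"),
                     terminals = c("a", "b"))
  ## no subtree-origin slots: empty child configuration
  E0 <- ec_set(ec_blank(c("a", "b")), "out", "a", "bag", "b")
  E0 <- ec_set(E0, "in", "b", "bag", "a")
  CL <- ec_child_conf(E0, ctx, "left")
  expect_true(all(is.na(CL)))

  ## left-origin slot carries over verbatim
  E1 <- ec_set(ec_blank(c("a", "b")), "out", "a", "left", "b")
  E1 <- ec_set(E1, "in", "b", "left", "a")
  CL1 <- ec_child_conf(E1, ctx, "left")
  expect_equal(unname(CL1["out", "a"]), "b")
  expect_equal(unname(CL1["in", "b"]), "a")
  expect_true(all(is.na(ec_child_conf(E1, ctx, "right"))))

  ## mixed origins on one vertex: each side sees only its own slot
  E2 <- ec_set(ec_blank(c("a", "b")), "in", "a", "left", "NONE")
  E2 <- ec_set(E2, "out", "a", "right", "NONE")
  expect_equal(unname(ec_child_conf(E2, ctx, "left")["in", "a"]), "NONE")
  expect_true(is.na(ec_child_conf(E2, ctx, "left")["out", "a"]))
  expect_equal(unname(ec_child_conf(E2, ctx, "right")["out", "a"]), "NONE")
})

test_that("penalties count merged components once", {
  ## two child paths joined into one component by a bag edge:
  ## ... -> a (left subtree), edge (a, b), b -> ... (right subtree)
  ctx <- bag_context(c("a", "b"), rbind(c("a", "b")),
                     left = c("a", "b"), right = c("a", "b"),
                     terminals = character(0))
  E <- ec_blank(c("a", "b"))
  E <- ec_set(E, "in", "a", "left", "NONE")    # path arrives at a from left
  E <- ec_set(E, "out", "a", "bag", "b")
  E <- ec_set(E, "in", "b", "bag", "a")
  E <- ec_set(E, "out", "b", "right", "NONE")  # continues into the right
  expect_true(ec_is_valid(E, ctx))
  CL <- ec_child_conf(E, ctx, "left")
  CR <- ec_child_conf(E, ctx, "right")
  expect_equal(ec_penalties(E, CL, CR, ctx, c = 2), 2)   # -c + c + c

  ## a fresh path lying entirely inside the bag, children empty
  E2 <- ec_set(ec_blank(c("a", "b")), "out", "a", "bag", "b")
  E2 <- ec_set(E2, "in", "b", "bag", "a")
  empty <- ec_child_conf(E2, ctx, "left")
  expect_equal(ec_penalties(E2, empty, empty, ctx, c = 2), -2)

  ## nothing used: no correction
  E3 <- ec_blank(c("a", "b"))
  expect_equal(ec_penalties(E3, empty, empty, ctx, c = 2), 0)
})

test_that("weight corrections add new vertices and cancel double counts", {
  ctx <- bag_context(c("a", "b", "v"), rbind(c("a", "v"), c("v", "b")),
                     left = c("a", "b", "v"), right = c("a", "b", "v"),
                     terminals = character(0))
  w <- c(a = 1, b = 1, v = 7)
  ## v used only via two bag edges: +w(v)
  E <- ec_blank(c("a", "b", "v"))
  E <- ec_set(E, "out", "a", "bag", "v"); E <- ec_set(E, "in", "v", "bag", "a")
  E <- ec_set(E, "out", "v", "bag", "b"); E <- ec_set(E, "in", "b", "bag", "v")
  expect_equal(ec_weight_delta(E, ctx, w), 1 + 7 + 1)

  ## v used in both subtrees: -w(v)
  E2 <- ec_blank(c("a", "b", "v"))
  E2 <- ec_set(E2, "in", "v", "left", "NONE")
  E2 <- ec_set(E2, "out", "v", "right", "NONE")
  expect_equal(ec_weight_delta(E2, ctx, w), -7)

  ## one subtree slot and one bag slot: counted in the child, no correction
  E3 <- ec_blank(c("a", "b", "v"))
  E3 <- ec_set(E3, "in", "v", "left", "NONE")
  E3 <- ec_set(E3, "out", "v", "bag", "b")
  E3 <- ec_set(E3, "in", "b", "bag", "v")
  expect_equal(ec_weight_delta(E3, ctx, w), 1)  # only b is new
})

test_that("treewidth solver handles the worked examples end to end", {
  g2 <- weighted_graph(c("a", "b"), rbind(c("a", "b")), c(a = -1, b = -3))
  r2 <- solve_treewidth(g2, single_bag_td(g2), 1)
  expect_equal(r2$score, 0)
  expect_length(r2$path_set$paths, 0L)

  g1 <- weighted_graph("v", NULL, c(v = 5))
  r1 <- solve_treewidth(g1, single_bag_td(g1), 2)
  expect_equal(r1$score, 3)
  expect_identical(r1$path_set$paths, list("v"))

  g3 <- sequence_graph(c(5, -2, 3))
  r3 <- solve_treewidth(g3, bag_per_edge_td(g3), 1)
  expect_equal(r3$score, 6)
  expect_equal(r3$score, solve_sequence(c(5, -2, 3), 1)$score)
})

test_that("treewidth optimum equals the oracle on random instances", {
  for (i in 1:40) {
    directed <- i %% 2 == 0
    n <- sample(2:7, 1)
    mcap <- if (directed) n * (n - 1) else n * (n - 1) / 2
    inst <- generate_random_instance("generic", n = n,
                                     m = sample(0:min(10L, mcap), 1),
                                     directed = directed, seed = 5000 + i)
    g <- inst$graph
    for (cc in c(0, 0.5, 1, 2)) {
      r <- solve_treewidth(g, single_bag_td(g), cc)
      expect_equal(r$score, solve_bruteforce(g, cc)$score,
                   info = sprintf("seed %d c %g", 5000 + i, cc))
      expect_empty_report(validate_path_set(r$path_set, g, cc))
      expect_equal(r$path_set$total_score, r$score, tolerance = 1e-9)
    }
  }
})

test_that("the optimum does not depend on the decomposition", {
  for (i in 1:10) {
    inst <- generate_random_instance("dag_from_paths", n = sample(4:7, 1),
                                     k = 3, seed = 5200 + i)
    g <- inst$graph
    td1 <- single_bag_td(g)
    td2 <- from_path_cover(g, inst$cover)
    for (cc in c(0.5, 1)) {
      expect_equal(solve_treewidth(g, td1, cc)$score,
                   solve_treewidth(g, td2, cc)$score)
    }
  }
  for (i in 1:10) {
    inst <- generate_random_instance("ttsp", leaf_edges = sample(2:8, 1),
                                     seed = 5300 + i)
    td1 <- single_bag_td(inst$graph)
    td2 <- ttsp_to_tree_decomposition(inst$ttsp)
    expect_equal(solve_treewidth(inst$graph, td1, 1)$score,
                 solve_treewidth(inst$graph, td2, 1)$score)
  }
})

test_that("per-bag table sizes respect the configuration-count bound", {
  for (i in 1:10) {
    inst <- generate_random_instance("ttsp", leaf_edges = sample(3:15, 1),
                                     seed = 5400 + i)
    td <- ttsp_to_tree_decomposition(inst$ttsp)
    d <- solve_treewidth(inst$graph, td, 1)$diagnostics
    expect_true(all(d$n_configs <= (d$n_terminals + 2)^(2 * d$n_terminals)))
    expect_true(all(d$n_extended <= (3 * d$bag_size + 4)^(2 * d$bag_size)))
  }
})

test_that("solve_msps dispatches and cross-validates across methods", {
  g <- sequence_graph(c(5, -2, 3))
  r <- solve_msps(g, c = 1)
  expect_equal(r$method, "sequence")
  expect_equal(r$score, 6)
  expect_equal(solve_msps(g, c = 1, method = "bruteforce")$score, 6)
  expect_equal(solve_msps(g, c = 1, method = "treewidth",
                          td = bag_per_edge_td(g))$score, 6)

  r2 <- solve_msps(eds = "{AC,G}", char_weight = c(A = -1, C = 1, G = 1),
                   c = 0.5)
  tg <- eds_to_ttsp("{AC,G}", c(A = -1, C = 1, G = 1))
  r3 <- solve_msps(tg$graph, c = 0.5, method = "treewidth",
                   td = ttsp_to_tree_decomposition(tg))
  r4 <- solve_msps(tg$graph, c = 0.5, method = "bruteforce")
  expect_equal(r2$method, "ttsp")
  expect_equal(r2$score, r3$score)
  expect_equal(r2$score, r4$score)

  expect_equal(solve_msps(weighted_graph(character(0)), c = 1)$score, 0)
})

test_that("runtime grows roughly linearly in the number of bags at fixed width", {
  inst1 <- generate_random_instance("ttsp", leaf_edges = 60, seed = 42)
  inst2 <- generate_random_instance("ttsp", leaf_edges = 120, seed = 42)
  td1 <- ttsp_to_tree_decomposition(inst1$ttsp)
  td2 <- ttsp_to_tree_decomposition(inst2$ttsp)
  t1 <- system.time(for (k in 1:5) solve_treewidth(inst1$graph, td1, 1))[["elapsed"]]
  t2 <- system.time(for (k in 1:5) solve_treewidth(inst2$graph, td2, 1))[["elapsed"]]
  ## doubling the instance should not blow up the time; generous cap to keep
  ## the check robust on a loaded machine
  expect_lt(t2, max(0.5, 6 * t1))
})
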