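test_that("modularity matches hand evaluations and igraph", {
  net <- two_triangles()
  memb <- stats::setNames(c(1, 1, 1, 2, 2, 2),
                          c("A1", "A2", "A3", "B1", "B2", "B3"))
  expect_equal(network_modularity(net, memb), 2 * (3 / 7 - (7 / 14)^2),
               tolerance = 1e-12)

  one <- stats::setNames(rep(1, 6), names(memb))
  expect_equal(network_modularity(net, one), 0, tolerance = 1e-12)

  tri <- cycle3()
  singles <- stats::setNames(1:3, c("C1", "C2", "C3"))
  expect_equal(network_modularity(tri, singles), -1 / 3, tolerance = 1e-12)

  for (s in 1:4) {
    net <- random_net(10, 0.3, seed = s)
    set.seed(s)
    memb <- stats::setNames(sample(1:3, 10, replace = TRUE), net_nodes(net))
    ug <- igraph::as_undirected(net$graph, mode = "collapse")
    expect_equal(network_modularity(net, memb),
                 igraph::modularity(ug, memb[igraph::V(ug)$name]),
                 tolerance = 1e-12)
  }
  expect_error(network_modularity(net, stats::setNames(integer(), character())),
               "empty")
})

test_that("simulated annealing recovers planted cliques deterministically", {
  net <- two_cliques()
  p <- sa_partition(net, seed = 1)
  expect_equal(p$modularity, 2 * (10 / 21 - (21 / 42)^2), tolerance = 1e-9)
  expect_equal(p$n_modules, 2L)
  split_by <- split(names(p$assignment), p$assignment)
  expect_setequal(vapply(split_by, function(g)
    paste(sort(unique(substr(g, 1, 1))), collapse = ""), ""), c("A", "B"))

  p2 <- sa_partition(net, seed = 1)
  expect_identical(p$assignment, p2$assignment)

  expect_error(sa_partition(net, cooling = 1.5), "cooling")
})

test_that("incrementally tracked modularity matches from-scratch recomputation", {
  for (s in 1:3) {
    net <- random_net(sample(15:30, 1), 0.15, seed = s + 40)
    p <- sa_partition(net, seed = s, check = TRUE)
    expect_lt(p$max_check_err, 1e-12)
    expect_equal(network_modularity(net, p$assignment), p$modularity,
                 tolerance = 1e-12)
    expect_gte(p$modularity, 0)  # at least as good as the single module
  }
})

test_that("expansion follows the neighbour-majority rules", {
  # pendant node joins its only adjacent module
  net <- metabolic_network(arcs_df(c("A1", "A2", "P"), c("A2", "A1", "A1")))
  part <- structure(list(assignment = c(A1 = 1L, A2 = 1L)), class = "partition")
  ex <- expand_partition(net, part)
  expect_equal(ex$assignment[["P"]], 1L)

  # majority rule: 2 neighbours in module 2, 1 in module 1
  net2 <- metabolic_network(arcs_df(c("A1", "B1", "B2", "X", "X", "B1"),
                                    c("A2", "X", "X", "A1", "B1", "B2")))
  part2 <- structure(list(assignment = c(A1 = 1L, A2 = 1L, B1 = 2L, B2 = 2L)),
                     class = "partition")
  ex2 <- expand_partition(net2, part2)
  expect_equal(ex2$assignment[["X"]], 2L)

  # tie between modules 1 and 2 -> lowest module index
  net3 <- metabolic_network(arcs_df(c("A1", "B1", "X", "X"),
                                    c("A2", "B2", "A1", "B1")))
  part3 <- structure(list(assignment = c(A1 = 1L, A2 = 1L, B1 = 2L, B2 = 2L)),
                     class = "partition")
  expect_equal(expand_partition(net3, part3)$assignment[["X"]], 1L)

  # chains are absorbed wave by wave; disconnected nodes stay out
  net4 <- metabolic_network(arcs_df(c("A1", "A1", "Y", "Q"),
                                    c("A2", "Y", "Z", "R")))
  part4 <- structure(list(assignment = c(A1 = 1L, A2 = 1L)), class = "partition")
  ex4 <- expand_partition(net4, part4)
  expect_equal(ex4$assignment[["Y"]], 1L)
  expect_equal(ex4$assignment[["Z"]], 1L)
  expect_false("Q" %in% names(ex4$assignment))

  # originally assigned nodes are never reassigned
  expect_equal(ex4$assignment[names(part4$assignment)], part4$assignment)
})

test_that("module compositions sit on the simplex with fractional weights", {
  net <- metabolic_network(
    arcs_df(c("C1", "C2", "C3"), c("C2", "C3", "C4")),
    compound_pathways = list(C1 = "p1", C2 = "p1", C3 = c("p1", "p2")),
    pathway_category = c(p1 = "X", p2 = "Y"))
  part <- structure(list(assignment = c(C1 = 1L, C2 = 1L, C3 = 2L, C4 = 3L)),
                    class = "partition")
  comp <- module_composition(net, part)
  expect_equal(rowSums(comp), rep(1, 3), ignore_attr = TRUE)
  # module 1: both nodes pure category X
  expect_equal(comp["1", "X"], 1)
  # module 2: single node split between p1 (X) and p2 (Y)
  expect_equal(comp["2", "X"], 0.5)
  expect_equal(comp["2", "Y"], 0.5)
  # module 3: unmapped node -> "other"
  expect_equal(comp["3", "other"], 1)

  # node in a category plus an unmapped partner: 0.5 / 0.5
  part2 <- structure(list(assignment = c(C1 = 1L, C4 = 1L)), class = "partition")
  comp2 <- module_composition(net, part2)
  expect_equal(comp2["1", "X"], 0.5)
  expect_equal(comp2["1", "other"], 0.5)
})

test_that("Ward clustering cuts composition vectors as expected", {
  M <- rbind("1" = c(1, 0), "2" = c(1, 0), "3" = c(0, 1))
  colnames(M) <- c("X", "Y")
  cut <- ward_cluster(M, 2)
  expect_equal(cut$assignment[["1"]], cut$assignment[["2"]])
  expect_false(cut$assignment[["1"]] == cut$assignment[["3"]])
  expect_equal(cut$tree$height[1], 0)          # identical vectors merge at 0
  expect_true(all(diff(cut$tree$height) >= -1e-12))  # monotone heights

  singletons <- ward_cluster(M, 3)
  expect_equal(sort(unname(singletons$assignment)), 1:3)
  expect_error(ward_cluster(M, 4), "module count")
})

test_that("modularity z-scores separate planted from random structure", {
  net <- two_cliques()
  p <- sa_partition(net, seed = 2)
  z <- partition_null_z(net, p, R = 50, seed = 3)
  expect_gt(z$z, 2.33)
  z2 <- partition_null_z(net, p, R = 50, seed = 3)
  expect_identical(z$z, z2$z)

  # random balanced partition on a random graph carries no signal
  ok <- 0L
  for (s in 1:10) {
    rnet <- random_net(16, 0.25, seed = s + 60)
    memb <- stats::setNames(rep(1:4, each = 4), net_nodes(rnet))
    z3 <- partition_null_z(rnet, memb, R = 50, seed = s)
    ok <- ok + (abs(z3$z) < 2.33)
  }
  expect_gte(ok, 8L)
})
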