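test_that("reaction lines parse into records with currency filtering", {
  rec <- parse_reaction_list(c("R00001: 00010: C1 + C2 => C3",
                               "R00002: 00020: C1 <=> C4",
                               "# comment", "",
                               "R00003: 00010: C1 + H2O => C5"),
                             currency = "H2O")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$direction, c("forward", "bidirectional", "forward"))
  expect_equal(rec$substrates[[1]], c("C1", "C2"))
  expect_equal(rec$products[[1]], "C3")
  expect_equal(rec$substrates[[3]], "C1")  # H2O removed
  expect_equal(rec$products[[3]], "C5")

  # reverse arrow keeps sides as written
  rev <- parse_reaction_list("R1: 00010: C1 <= C2")
  expect_equal(rev$direction, "reverse")
  expect_equal(rev$substrates[[1]], "C1")
  expect_equal(rev$products[[1]], "C2")

  # a record whose side empties after currency removal is dropped
  gone <- parse_reaction_list(c("R1: 00010: H2O => C2", "R2: 00010: C1 => C2"),
                              currency = "H2O")
  expect_equal(gone$reaction_id, "R2")
})

test_that("malformed reaction lines raise errors naming the line", {
  expect_error(parse_reaction_list("not a reaction"), "line 1")
  expect_error(parse_reaction_list(c("R1: 00010: C1 => C2", "R2: garbage")),
               "line 2")
  expect_error(parse_reaction_list("R1: 00010: C1 -> C2"), "line 1")
})

test_that("build_network expands substrate x product arc sets", {
  rec <- parse_reaction_list("R1: 00010: C1 => C2")
  net <- build_network(rec)
  expect_setequal(net_nodes(net), c("C1", "C2"))
  expect_equal(nrow(net_arcs(net)), 1L)

  bid <- build_network(parse_reaction_list("R1: 00010: C1 <=> C2"))
  expect_equal(nrow(net_arcs(bid)), 2L)

  multi <- build_network(parse_reaction_list(
    c("R1: 00010: C1 + C2 => C3", "R2: 00010: C3 => C1")))
  expect_setequal(net_nodes(multi), c("C1", "C2", "C3"))
  arcs <- net_arcs(multi)
  expect_equal(nrow(arcs), 3L)
  expect_true(all(paste(arcs$from, arcs$to) %in%
                  c("C1 C3", "C2 C3", "C3 C1")))

  # reverse direction adds product -> substrate arcs
  rnet <- build_network(parse_reaction_list("R1: 00010: C1 <= C2"))
  expect_equal(net_arcs(rnet), arcs_df("C2", "C1"))

  # self-loops dropped, duplicates collapsed
  dup <- build_network(parse_reaction_list(
    c("R1: 00010: C1 => C1 + C2", "R2: 00010: C1 => C2")))
  expect_equal(nrow(net_arcs(dup)), 1L)

  expect_error(build_network(parse_reaction_list("R1: 00010: H2O => H2O + X",
                                                 currency = c("H2O", "X"))),
               "empty network")
})

test_that("currency removal never increases node or arc counts", {
  sim <- generate_synthetic(synth_config(seed = 11, currency_count = 4L))
  with_cur <- build_network(parse_reaction_list(sim$reactions,
                                                currency = sim$currency))
  without <- build_network(parse_reaction_list(sim$reactions))
  expect_lte(length(net_nodes(with_cur)), length(net_nodes(without)))
  expect_lte(nrow(net_arcs(with_cur)), nrow(net_arcs(without)))
})

test_that("bow-tie decomposition partitions the node set", {
  net <- metabolic_network(arcs_df(c("C1", "C2", "C3", "C0", "C8"),
                                   c("C2", "C3", "C1", "C1", "C9")))
  bt <- bow_tie(net)
  expect_setequal(bt$gsc, c("C1", "C2", "C3"))
  expect_equal(bt$in_set, "C0")
  expect_length(bt$out_set, 0)
  expect_length(bt$tendrils, 0)
  expect_setequal(bt$isolated, c("C8", "C9"))

  tri <- bow_tie(cycle3())
  expect_setequal(tri$gsc, c("C1", "C2", "C3"))
  expect_length(unlist(tri[-1]), 0)

  # size-1 SCC tie broken by smallest node id
  expect_equal(bow_tie(metabolic_network(arcs_df("C1", "C2")))$gsc, "C1")

  # partition property on random synthetic networks
  for (s in 1:5) {
    net <- generate_synthetic(synth_config(seed = s))$network
    bt <- bow_tie(net)
    expect_setequal(unlist(bt, use.names = FALSE), net_nodes(net))
    expect_equal(sum(lengths(bt)), length(net_nodes(net)))
    # gsc is strongly connected
    sub <- igraph::induced_subgraph(net$graph, bt$gsc)
    expect_equal(igraph::components(sub, mode = "strong")$no, 1L)
  }
})

test_that("graph formats round-trip", {
  net <- metabolic_network(
    arcs_df(c("C1", "C2", "C3"), c("C2", "C3", "C1")),
    compound_pathways = list(C1 = "00010", C2 = c("00010", "00020")),
    pathway_category = c("00010" = "Amino Acid Metabolism",
                         "00020" = "Lipid Metabolism"))
  f <- tempfile(fileext = ".graphml")
  write_network(net, f, "graphml")
  back <- read_network(f, "graphml")
  expect_setequal(net_nodes(back), net_nodes(net))
  expect_equal(nrow(merge(net_arcs(back), net_arcs(net))), nrow(net_arcs(net)))
  expect_setequal(back$compound_pathways[["C2"]], c("00010", "00020"))
  expect_equal(back$pathway_category[["00020"]], "Lipid Metabolism")

  fs <- tempfile(fileext = ".sif")
  write_network(metabolic_network(arcs_df("C1", "C2")), fs, "sif")
  expect_equal(readLines(fs), "C1\trxn\tC2")

  fe <- tempfile(fileext = ".tsv")
  sim_net <- generate_synthetic(synth_config(seed = 2))$network
  write_network(sim_net, fe, "edgelist")
  expect_equal(length(readLines(fe)) - 1L, nrow(net_arcs(sim_net)))
  back2 <- read_network(fe, "edgelist")
  expect_setequal(net_nodes(back2), net_nodes(sim_net))

  expect_error(write_network(net, tempfile(), "gexf"))
})

test_that("mean in-degree equals mean out-degree equals arcs/nodes", {
  for (s in 1:5) {
    net <- generate_synthetic(synth_config(seed = s))$network
    deg <- node_degrees(net)
    ratio <- nrow(net_arcs(net)) / length(net_nodes(net))
    expect_equal(mean(deg$in_degree), ratio)
    expect_equal(mean(deg$out_degree), ratio)
  }
})
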