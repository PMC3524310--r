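test_that("generation is byte-deterministic given the seed", {
  a <- generate_synthetic(synth_config(seed = 42))
  b <- generate_synthetic(synth_config(seed = 42))
  expect_identical(a$reactions, b$reactions)
  expect_identical(a$compound_pathways, b$compound_pathways)
  expect_identical(a$truth$planted_differential, b$truth$planted_differential)
  expect_identical(a$truth$planted_target$compound, b$truth$planted_target$compound)
  c <- generate_synthetic(synth_config(seed = 43))
  expect_false(identical(a$reactions, c$reactions))
})

test_that("emitted files re-parse into the same network", {
  dir <- tempfile()
  sim <- generate_synthetic(synth_config(seed = 7), dir = dir)
  rec <- parse_reaction_list(file.path(dir, "reactions.lst"),
                             currency = sim$currency)
  net <- build_network(rec,
                       read_annotations(file.path(dir, "compound_pathways.tsv")),
                       read_categories(file.path(dir, "pathway_category.tsv")))
  expect_setequal(net_nodes(net), net_nodes(sim$network))
  expect_equal(nrow(net_arcs(net)), nrow(net_arcs(sim$network)))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$planted_enriched_pathway, sim$truth$planted_enriched_pathway)
})

test_that("no cross-pathway reactions means disconnected pathways", {
  sim <- generate_synthetic(synth_config(seed = 3, cross_pathway_reactions = 0L,
                                         isolated_component_count = 0L,
                                         currency_count = 0L))
  wc <- igraph::components(sim$network$graph, mode = "weak")
  expect_gte(wc$no, 5L)
})

test_that("zero currency leaves all reaction compounds in the network", {
  sim <- generate_synthetic(synth_config(seed = 5, currency_count = 0L))
  rec <- parse_reaction_list(sim$reactions, currency = character())
  all_compounds <- unique(unlist(c(rec$substrates, rec$products)))
  expect_setequal(net_nodes(sim$network),
                  intersect(all_compounds, net_nodes(sim$network)))
  expect_false(any(default_currency() %in% all_compounds))
})

test_that("planted partition beats size-matched random partitions", {
  for (s in 1:3) {
    sim <- generate_synthetic(synth_config(seed = s,
                                           intra_pathway_reactions = 14L,
                                           cross_pathway_reactions = 3L))
    net <- sim$network
    truth <- sim$truth$planted_modules
    memb <- truth[intersect(names(truth), net_nodes(net))]
    q_planted <- network_modularity(net, memb)
    set.seed(s)
    q_rand <- replicate(20, network_modularity(
      net, stats::setNames(sample(memb), names(memb))))
    expect_gt(q_planted, max(q_rand))
  }
})

test_that("plant_differential with hub_bias 0 samples uniformly", {
  net <- generate_synthetic(synth_config(seed = 1))$network
  pw <- "00010"
  counts <- table(unlist(lapply(1:2000, function(i)
    plant_differential(net, pw, 2L, 0L, hub_bias = 0, seed = i)$compound)))
  pool <- intersect(names(net$compound_pathways)[
    vapply(net$compound_pathways, function(p) pw %in% p, logical(1))],
    net_nodes(net))
  obs <- as.numeric(counts[pool])
  obs[is.na(obs)] <- 0
  expect_gt(stats::chisq.test(obs)$p.value, 0.01)
})

test_that("large hub_bias lifts set degree above the network mean", {
  ok <- 0L
  for (s in 1:20) {
    net <- generate_synthetic(synth_config(seed = s))$network
    d <- plant_differential(net, "00010", 8L, 12L, hub_bias = 1000,
                            seed = s + 100L)
    deg <- igraph::degree(net$graph, mode = "all")
    ok <- ok + (mean(deg[intersect(d$compound, net_nodes(net))]) >= mean(deg))
  }
  expect_gte(ok, 19L)
})

test_that("planting respects counts, regulation and feasibility", {
  net <- generate_synthetic(synth_config(seed = 2))$network
  d <- plant_differential(net, "00010", 5L, 0L, seed = 9)
  pool <- names(net$compound_pathways)[
    vapply(net$compound_pathways, function(p) "00010" %in% p, logical(1))]
  expect_true(all(d$compound %in% pool))
  expect_true(all(d$regulation %in% c(-1L, 1L)))
  expect_error(plant_differential(net, "00010", 1000L, 0L, seed = 1),
               "insufficient")

  tgt <- plant_target(net, d, 5L, seed = 4)
  expect_length(tgt$compound, 5L)
  expect_length(intersect(tgt$compound, d$compound), 0L)
  # every target member lies within directed distance 2 of the set
  D <- pmin(igraph::distances(net$graph, v = tgt$compound, to = d$compound,
                              mode = "out"),
            igraph::distances(net$graph, v = tgt$compound, to = d$compound,
                              mode = "in"))
  expect_true(all(apply(D, 1, min) <= 2))
})
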