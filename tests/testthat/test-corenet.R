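core_fixture <- function() {
  # pathway pA: C1-C2-C3-C4 chain; pathway pB: C5-C6; C9 unannotated
  metabolic_network(
    arcs_df(c("C1", "C2", "C3", "C5", "C4"),
            c("C2", "C3", "C4", "C6", "C9")),
    compound_pathways = list(C1 = "pA", C2 = "pA", C3 = "pA", C4 = "pA",
                             C5 = "pB", C6 = "pB"),
    pathway_category = c(pA = "Amino Acid Metabolism", pB = "Lipid Metabolism"))
}

test_that("core extraction prunes by radius around differential members", {
  net <- core_fixture()
  diff <- node_set(c("C1", "C5"), regulation = c(1L, -1L))

  r0 <- build_core(net, c("pA", "pB"), diff, radius = 0)
  expect_setequal(r0$attributes$compound, c("C1", "C5"))

  rinf <- build_core(net, "pA", diff, radius = Inf)
  expect_setequal(rinf$attributes$compound, c("C1", "C2", "C3", "C4"))

  r1 <- build_core(net, "pA", diff, radius = 1)
  expect_setequal(r1$attributes$compound, c("C1", "C2"))

  # radius growth is monotone
  sizes <- vapply(0:3, function(r)
    nrow(build_core(net, c("pA", "pB"), diff, radius = r)$attributes),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))

  # core is a subgraph of the background
  expect_true(all(r1$attributes$compound %in% net_nodes(net)))
  expect_true(all(paste(net_arcs(r1$network)$from, net_arcs(r1$network)$to) %in%
                  paste(net_arcs(net)$from, net_arcs(net)$to)))

  expect_error(build_core(net, "pB", node_set("C1"), radius = 1),
               "no differential member")
})

test_that("core node counts match an independent breadth-first search", {
  sim <- generate_synthetic(synth_config(seed = 13))
  net <- sim$network
  diff <- sim$truth$planted_differential
  pw <- sim$truth$planted_enriched_pathway
  members <- intersect(names(net$compound_pathways)[
    vapply(net$compound_pathways, function(p) pw %in% p, logical(1))],
    net_nodes(net))
  radius <- 2
  core <- build_core(net, pw, diff, radius = radius)
  # oracle: undirected BFS ball inside the pathway-induced subgraph
  sub <- igraph::induced_subgraph(net$graph, members)
  diff_in <- intersect(diff$compound, members)
  d <- igraph::distances(sub, v = diff_in, mode = "all")
  ball <- colnames(d)[apply(d, 2, min) <= radius]
  deg <- igraph::degree(igraph::induced_subgraph(sub, ball))
  expected <- union(names(deg)[deg > 0], diff_in)
  expect_setequal(core$attributes$compound, expected)
})

test_that("regulation and role annotations are attached and summarised", {
  net <- core_fixture()
  diff <- node_set(c("C1", "C3"), regulation = c(1L, -1L))
  core <- build_core(net, "pA", diff, radius = Inf)
  a <- core$attributes
  expect_equal(a$regulation[a$compound == "C1"], "up")
  expect_equal(a$regulation[a$compound == "C3"], "down")
  expect_equal(a$regulation[a$compound == "C2"], "unmeasured")

  expect_identical(annotate_roles(core, list())$attributes, a)

  tagged <- annotate_roles(core, list(neurotransmitter = c("C1", "C2"),
                                      neuroactive = "C2"))
  at <- tagged$attributes
  expect_equal(at$roles[at$compound == "C2"], "neurotransmitter|neuroactive")
  expect_warning(annotate_roles(core, list(neuroactive = "ZZZ")), "ignored")

  out <- capture.output(summary(tagged))
  expect_true(any(grepl("role-tagged compounds: 2 among 4", out)))
})

test_that("core networks export with attributes", {
  net <- core_fixture()
  core <- annotate_roles(
    build_core(net, "pA", node_set(c("C1", "C3"), c(1L, -1L)), radius = Inf),
    list(neuroactive = "C2"))
  f <- tempfile(fileext = ".graphml")
  write_core(core, f, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_true(all(c("regulation", "pathways", "roles") %in%
                  igraph::vertex_attr_names(g)))
  fs <- tempfile(fileext = ".sif")
  write_core(core, fs, "sif")
  expect_true(file.exists(paste0(fs, ".attrs.tsv")))
})
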