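test_that("hypergeometric upper tail matches closed forms", {
  expect_equal(hyper_tail(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(hyper_tail(100, 20, 10, 0), 1)
  expect_equal(round(hyper_tail(1386, 284, 32, 12), 3), 0.019)
  expect_error(hyper_tail(10, 11, 5, 1), "K")
  expect_error(hyper_tail(10, 5, 5, 6), "k")
})

test_that("upper tail agrees with direct summation and pmf normalisation", {
  set.seed(1)
  for (i in 1:20) {
    N <- sample(10:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hyper_tail(N, K, n, k), hyper_tail_direct(N, K, n, k),
                 tolerance = 1e-10)
    # pmf sums to one
    i_all <- max(0, n - (N - K)):min(n, K)
    expect_equal(sum(choose(K, i_all) * choose(N - K, n - i_all)) / choose(N, n),
                 1, tolerance = 1e-10)
  }
  # monotone non-increasing in k
  ks <- 0:10
  expect_true(all(diff(hyper_tail(50, 20, 15, ks)[ks <= min(20, 15)]) <= 0))
})

test_that("cluster enrichment counts population, hits and order correctly", {
  assignment <- stats::setNames(c(1L, 1L, 2L, 2L, 3L, 3L),
                                paste0("C", 1:6))
  cut <- structure(list(tree = NULL, k = 2L,
                        assignment = c("1" = 1L, "2" = 1L, "3" = 2L)),
                   class = "cluster_cut")
  diff <- node_set(c("C1", "C5"))
  ce <- cluster_enrichment(cut, assignment, diff)
  expect_equal(attr(ce, "N"), 6L)
  expect_equal(attr(ce, "n"), 2L)
  expect_equal(ce$p, sort(ce$p))
  row2 <- ce[ce$label == "cluster 2", ]
  expect_equal(row2$K, 2L)
  expect_equal(row2$k, 1L)

  # single cluster covering everything: K = N, k = n, p = 1
  cut1 <- structure(list(tree = NULL, k = 1L,
                         assignment = c("1" = 1L, "2" = 1L, "3" = 1L)),
                    class = "cluster_cut")
  ce1 <- cluster_enrichment(cut1, assignment, diff)
  expect_equal(ce1$K, 6L)
  expect_equal(ce1$p, 1)

  # differential set disjoint from the assigned nodes: k = 0, p = 1
  ce0 <- cluster_enrichment(cut, assignment, node_set("Z9"))
  expect_true(all(ce0$k == 0L))
  expect_true(all(ce0$p == 1))
})

test_that("pathway enrichment ranks a fully covered pathway first", {
  net <- generate_synthetic(synth_config(seed = 3))$network
  pw <- "00010"
  members <- intersect(names(net$compound_pathways)[
    vapply(net$compound_pathways, function(p) pw %in% p, logical(1))],
    net_nodes(net))
  pe <- pathway_enrichment(net, node_set(members))
  expect_equal(pe$label[1], pw)
  expect_equal(min(pe$p), pe$p[1])

  # a pathway without differential members scores p = 1
  other <- pe[pe$k == 0, ]
  expect_true(all(other$p == 1))

  expect_error(pathway_enrichment(net, members, population = "galaxy"))
})

test_that("reported enrichment ordering matches the K/k trade-off", {
  # the tryptophan-style row (K=81, k=8) must outrank the tyrosine-style
  # row (K=76, k=4) for any plausible population
  for (N in c(1386, 2200)) for (n in c(32, 49)) {
    expect_lt(hyper_tail(N, 81, n, 8), hyper_tail(N, 76, n, 4))
  }
})

test_that("enrichment is invariant to label and row order", {
  assignment <- stats::setNames(rep(1:3, each = 4), paste0("C", 1:12))
  cut <- structure(list(tree = NULL, k = 3L,
                        assignment = c("1" = 1L, "2" = 2L, "3" = 3L)),
                   class = "cluster_cut")
  diff <- node_set(c("C1", "C2", "C5"))
  ce <- cluster_enrichment(cut, assignment, diff)
  perm <- sample(names(assignment))
  ce2 <- cluster_enrichment(cut, assignment[perm], diff)
  expect_equal(ce$p, ce2$p)
})

test_that("planted pathway enrichment recovers at high rate", {
  hits <- 0L
  for (s in 1:25) {
    sim <- generate_synthetic(synth_config(seed = s))
    pe <- pathway_enrichment(sim$network, sim$truth$planted_differential)
    hits <- hits + (pe$label[1] == sim$truth$planted_enriched_pathway)
  }
  expect_gte(hits, 24L)
})
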