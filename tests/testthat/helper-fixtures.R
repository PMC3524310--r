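# Small graph fixtures (built in code) and independent oracles used to
# validate the package's implementations.

arcs_df <- function(from, to) data.frame(from = from, to = to,
                                         stringsAsFactors = FALSE)

# C1 -> C2 -> C3
path3 <- function() metabolic_network(arcs_df(c("C1", "C2"), c("C2", "C3")))

# directed 3-cycle
cycle3 <- function() metabolic_network(arcs_df(c("C1", "C2", "C3"),
                                               c("C2", "C3", "C1")))

# complete bidirectional triangle (all 6 arcs)
complete3 <- function() {
  v <- c("C1", "C2", "C3")
  e <- expand.grid(from = v, to = v, stringsAsFactors = FALSE)
  metabolic_network(e[e$from != e$to, ])
}

# two undirected triangles joined by one edge (7 undirected edges)
two_triangles <- function() metabolic_network(arcs_df(
  c("A1", "A2", "A3", "B1", "B2", "B3", "A1"),
  c("A2", "A3", "A1", "B2", "B3", "B1", "B1")))

# two 5-cliques joined by one edge
two_cliques <- function() {
  clique <- function(p) {
    e <- t(utils::combn(paste0(p, 1:5), 2))
    arcs_df(e[, 1], e[, 2])
  }
  metabolic_network(rbind(clique("A"), clique("B"), arcs_df("A1", "B1")))
}

# random weakly connected digraph as a metabolic_network
random_net <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p, directed = TRUE)
    if (igraph::is_connected(g, mode = "weak") && igraph::ecount(g) > 0) break
  }
  el <- igraph::as_edgelist(g)
  metabolic_network(arcs_df(paste0("C", el[, 1]), paste0("C", el[, 2])))
}

# ---- independent oracles -------------------------------------------------

# undirected simple projection as an edge matrix of node indices
undirected_edges <- function(net) {
  ug <- igraph::as_undirected(net$graph, mode = "collapse")
  list(el = igraph::as_edgelist(ug, names = FALSE),
       deg = as.numeric(igraph::degree(ug)),
       L = igraph::ecount(ug),
       nodes = igraph::V(ug)$name)
}

# modularity evaluated directly from the formula (no package code)
q_direct <- function(ue, memb_idx) {
  if (ue$L == 0) return(0)
  m1 <- memb_idx[ue$el[, 1]]
  m2 <- memb_idx[ue$el[, 2]]
  K <- max(memb_idx)
  l_s <- tabulate(m1[m1 == m2], nbins = K)
  d_s <- vapply(seq_len(K), function(s) sum(ue$deg[memb_idx == s]), numeric(1))
  sum(l_s / ue$L - (d_s / (2 * ue$L))^2)
}

# exhaustive maximum modularity over all partitions (restricted growth
# strings; Bell-number search, feasible for n <= 8)
exhaustive_qmax <- function(net) {
  ue <- undirected_edges(net)
  n <- length(ue$nodes)
  best <- -Inf
  rec <- function(rgs, mx) {
    if (length(rgs) == n) {
      q <- q_direct(ue, rgs)
      if (q > best) best <<- q
      return()
    }
    for (v in seq_len(mx + 1)) rec(c(rgs, v), max(mx, v))
  }
  rec(integer(0), 0L)
  best
}

# directed betweenness by explicit enumeration of all simple paths
# (feasible for <= 7 nodes); returns raw pair-dependency sums
brute_betweenness <- function(net) {
  nm <- net_nodes(net)
  n <- length(nm)
  adj <- lapply(nm, function(v)
    names(igraph::neighbors(net$graph, v, mode = "out")))
  names(adj) <- nm
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) { out[[length(out) + 1]] <<- path; return() }
      for (w in setdiff(adj[[last]], path)) walk(c(path, w))
    }
    walk(s)
    out
  }
  b <- stats::setNames(numeric(n), nm)
  for (s in nm) for (t in setdiff(nm, s)) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- lengths(paths) - 1L
    short <- paths[lens == min(lens)]
    sigma <- length(short)
    for (p in short) for (v in setdiff(p, c(s, t))) b[v] <- b[v] + 1 / sigma
  }
  b
}

# hypergeometric upper tail by direct summation of the pmf
hyper_tail_direct <- function(N, K, n, k) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
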