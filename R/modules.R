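#' Newman modularity of a partition
#'
#' Modularity is evaluated on the undirected simple projection of the
#' network restricted to the partitioned nodes:
#' `Q = sum_s [ l_s/L - (d_s/2L)^2 ]` with `l_s` the within-module edge
#' count, `d_s` the module degree sum and `L` the total edge count.
#'
#' @param net a [metabolic_network()].
#' @param membership named vector (node id -> module label) covering the
#'   node subset to score; a [partition][sa_partition()] object is also
#'   accepted.
#' @return modularity in `[-1, 1]` (0 when the projection has no edges).
#' @export
network_modularity <- function(net, membership) {
  stopifnot(inherits(net, "metabolic_network"))
  if (inherits(membership, "partition")) membership <- membership$assignment
  if (length(membership) == 0L) stop("empty partition")
  if (is.null(names(membership))) stop("membership must be named by node id")
  ug <- undirected_projection(net, names(membership))
  L <- igraph::ecount(ug)
  if (L == 0L) return(0)
  lab <- as.character(membership[igraph::V(ug)$name])
  el <- igraph::as_edgelist(ug, names = TRUE)
  m1 <- as.character(membership[el[, 1L]])
  m2 <- as.character(membership[el[, 2L]])
  same <- m1 == m2
  deg <- igraph::degree(ug)
  d_by <- tapply(deg, lab, sum)
  l_full <- stats::setNames(rep(0, length(d_by)), names(d_by))
  if (any(same)) {
    l_by <- tapply(rep(1, sum(same)), m1[same], sum)
    l_full[names(l_by)] <- l_by
  }
  sum(l_full / L - (d_by / (2 * L))^2)
}

undirected_projection <- function(net, nodes = NULL) {
  g <- net$graph
  if (!is.null(nodes)) {
    miss <- setdiff(nodes, igraph::V(g)$name)
    if (length(miss)) stop("membership names node(s) absent from network: ",
                           paste(utils::head(miss, 3L), collapse = ", "))
    g <- igraph::induced_subgraph(g, nodes)
  }
  igraph::as_undirected(g, mode = "collapse")
}

#' Decompose a network into modules by simulated annealing
#'
#' Maximises Newman modularity on the undirected simple projection by
#' simulated annealing from a singleton start. At each temperature `T`,
#' `f*S^2` single-node reassignments and `f*S` collective proposals
#' (module merges and refined bisection splits; `S` = current module
#' count) are attempted and accepted with probability
#' `min(1, exp(dQ/T))`; `T` is multiplied by `cooling` until fewer than
#' 0.1% of proposals are accepted for three consecutive temperatures. The
#' best partition encountered is returned. Typically applied to the
#' network with its isolated bow-tie subset removed
#' (see [remove_isolated()]).
#'
#' @param net a [metabolic_network()].
#' @param T0 initial temperature; `NULL` picks it automatically so that
#'   roughly half of the initial downhill proposals are accepted.
#' @param cooling geometric cooling factor in (0, 1).
#' @param f moves-per-temperature multiplier.
#' @param seed integer seed; the run is fully deterministic given it.
#' @param restarts number of independent annealing runs (seeds derived
#'   from `seed`); the partition with the highest modularity is kept.
#'   Annealing is stochastic, so a few restarts buy noticeably more
#'   reliable optima at linear cost.
#' @param check when `TRUE`, the incrementally tracked modularity is
#'   verified against a from-scratch recomputation after every accepted
#'   move (slow; for validation on small graphs).
#' @return object of class `partition`: list with `assignment` (named
#'   integer, module indices 1..S in order of first appearance over the
#'   node order), `modularity`, `n_modules`, `seed`, `T0`,
#'   `temperatures`, and `max_check_err` when `check = TRUE`.
#' @export
sa_partition <- function(net, T0 = NULL, cooling = 0.995, f = 1,
                         seed = 1L, restarts = 3L, check = FALSE) {
  stopifnot(inherits(net, "metabolic_network"))
  if (!is.numeric(cooling) || cooling <= 0 || cooling >= 1)
    stop("cooling factor must be in (0, 1)")
  if (restarts < 1L) stop("need at least one annealing run")
  ug <- undirected_projection(net)
  nm <- igraph::V(ug)$name
  el <- igraph::as_edgelist(ug, names = FALSE)
  res <- NULL
  for (r in seq_len(restarts)) {
    run <- .sa_anneal(length(nm),
                      as.integer(el[, 1L] - 1L), as.integer(el[, 2L] - 1L),
                      if (is.null(T0)) NA_real_ else as.numeric(T0),
                      as.numeric(cooling), as.numeric(f),
                      as.integer(seed) + (r - 1L) * 7919L,
                      isTRUE(check))
    if (is.null(res) || run$modularity > res$modularity) res <- run
  }
  assignment <- stats::setNames(as.integer(res$membership), nm)
  structure(list(assignment = assignment,
                 modularity = res$modularity,
                 n_modules = length(unique(assignment)),
                 seed = as.integer(seed), T0 = res$T0,
                 temperatures = res$temperatures,
                 max_check_err = if (isTRUE(check)) res$max_check_err else NA_real_),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d nodes in %d modules, modularity = %.6f\n",
              length(x$assignment), x$n_modules, x$modularity))
  invisible(x)
}

as_assignment <- function(partition) {
  if (inherits(partition, "partition")) partition$assignment else partition
}

#' Expand a partition to adjacent unassigned nodes
#'
#' Iteratively absorbs nodes outside the partition that touch it: a node
#' directly connected (in either arc direction) to exactly one module
#' joins it; a node touching several modules joins the one containing the
#' most of its neighbours, ties going to the lowest module index. Waves
#' repeat until no further node can be attached; nodes never reached
#' (e.g. the isolated bow-tie subset) stay unassigned. Originally
#' assigned nodes are never reassigned.
#'
#' @param net a [metabolic_network()] (the full background network).
#' @param partition a [partition][sa_partition()] over a node subset.
#' @return a `partition` object over the enlarged node set, with
#'   modularity recomputed on it.
#' @export
expand_partition <- function(net, partition) {
  stopifnot(inherits(net, "metabolic_network"))
  assignment <- as_assignment(partition)
  if (!length(assignment)) stop("empty partition")
  ug <- undirected_projection(net)
  nbrs <- igraph::adjacent_vertices(ug, igraph::V(ug))
  nbrs <- lapply(nbrs, names)
  names(nbrs) <- igraph::V(ug)$name
  repeat {
    unassigned <- setdiff(names(nbrs), names(assignment))
    if (!length(unassigned)) break
    wave <- list()
    for (v in unassigned) {
      hit <- assignment[intersect(nbrs[[v]], names(assignment))]
      if (!length(hit)) next
      counts <- table(hit)
      best <- max(counts)
      wave[[v]] <- min(as.integer(names(counts)[counts == best]))
    }
    if (!length(wave)) break
    assignment <- c(assignment,
                    stats::setNames(as.integer(unlist(wave)), names(wave)))
  }
  structure(list(assignment = assignment,
                 modularity = network_modularity(net, assignment),
                 n_modules = length(unique(assignment)),
                 seed = if (inherits(partition, "partition")) partition$seed
                        else NA_integer_),
            class = "partition")
}

#' Pathway-composition vectors of modules
#'
#' For every module, counts (node, category) incidences: a node annotated
#' to `p` pathways contributes weight `1/p` to each pathway's category
#' (categories collapse by summation), and a node with no pathway
#' annotation contributes 1 to the `"other"` category, as does a pathway
#' with no category label. Rows are normalised to sum to 1.
#'
#' @param net a [metabolic_network()] carrying the annotation maps.
#' @param partition a [partition][sa_partition()] or named assignment.
#' @return matrix of class `module_composition` (modules x categories,
#'   rows on the simplex).
#' @export
module_composition <- function(net, partition) {
  stopifnot(inherits(net, "metabolic_network"))
  assignment <- as_assignment(partition)
  if (!length(assignment)) stop("empty partition")
  cats_of <- function(v) {
    pw <- net$compound_pathways[[v]]
    if (is.null(pw) || !length(pw)) return(c(other = 1))
    cat_lab <- net$pathway_category[pw]
    cat_lab[is.na(cat_lab)] <- "other"
    w <- rep(1 / length(pw), length(pw))
    tapply(w, cat_lab, sum)
  }
  contribs <- lapply(names(assignment), cats_of)
  all_cats <- sort(unique(unlist(lapply(contribs, names))))
  mods <- sort(unique(assignment))
  M <- matrix(0, length(mods), length(all_cats),
              dimnames = list(as.character(mods), all_cats))
  for (i in seq_along(contribs)) {
    m <- as.character(assignment[[i]])
    M[m, names(contribs[[i]])] <- M[m, names(contribs[[i]])] + contribs[[i]]
  }
  M <- M / rowSums(M)
  class(M) <- c("module_composition", class(M))
  M
}

#' @export
plot.module_composition <- function(x, order = NULL, ...) {
  M <- unclass(x)
  if (!is.null(order)) M <- M[order, , drop = FALSE]
  graphics::barplot(t(M), col = grDevices::hcl.colors(ncol(M), "Set 2"),
                    legend.text = colnames(M),
                    args.legend = list(x = "topright", cex = 0.7, bty = "n"),
                    las = 2, ylab = "proportion of biological process", ...)
  invisible(x)
}

#' Ward clustering of module composition vectors
#'
#' Agglomerates modules by Ward linkage (`ward.D2`) on the Euclidean
#' distances between their pathway-composition vectors and cuts the tree
#' into `k` clusters. Cluster ids are numbered by left-to-right tree
#' traversal order.
#'
#' @param composition a [module_composition()] matrix.
#' @param k number of clusters (`1 <= k <=` number of modules).
#' @return object of class `cluster_cut`: list with `tree` (an
#'   [stats::hclust]), `k` and `assignment` (named integer,
#'   module -> cluster id).
#' @export
ward_cluster <- function(composition, k) {
  M <- unclass(composition)
  if (k < 1L || k > nrow(M)) stop("k must be between 1 and the module count")
  tree <- stats::hclust(stats::dist(M, method = "euclidean"),
                        method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  # renumber clusters in tree-traversal order
  first_seen <- unique(raw[tree$order])
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  assignment <- stats::setNames(as.integer(relabel[as.character(raw)]),
                                names(raw))
  structure(list(tree = tree, k = as.integer(k), assignment = assignment),
            class = "cluster_cut")
}

#' @export
print.cluster_cut <- function(x, ...) {
  cat("Ward cut of", length(x$assignment), "modules into", x$k, "clusters\n")
  print(split(names(x$assignment), x$assignment))
  invisible(x)
}

#' Modularity Z-score against size-preserving random partitions
#'
#' Null model: `R` random reassignments of the observed module labels over
#' the same nodes (a uniform permutation, preserving the module-size
#' multiset); the observed modularity is standardised against their
#' modularities.
#'
#' @param net a [metabolic_network()].
#' @param partition a [partition][sa_partition()] or named assignment.
#' @param R number of random decompositions.
#' @param seed integer seed.
#' @return a [z_score()] object, with the null values in
#'   `attr(, "null")`.
#' @export
partition_null_z <- function(net, partition, R = 50L, seed = 1L) {
  assignment <- as_assignment(partition)
  if (R < 2L) stop("need at least 2 random decompositions")
  obs <- network_modularity(net, assignment)
  vals <- with_seed(seed, vapply(seq_len(R), function(i) {
    network_modularity(net, stats::setNames(sample(assignment),
                                            names(assignment)))
  }, numeric(1L)))
  nd <- structure(list(statistic_name = "modularity", replicates = R,
                       values = vals, mean = mean(vals),
                       sd = stats::sd(vals), seed = seed),
                  class = "null_distribution")
  out <- z_score(obs, nd)
  attr(out, "null") <- nd
  out
}
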