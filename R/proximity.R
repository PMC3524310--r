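#' Connectivity between two metabolite sets
#'
#' Counts unordered cross pairs `{a, b}` (a in A, b in B, after removing
#' shared members from both sets) joined by an arc in either direction.
#'
#' @param net a [metabolic_network()].
#' @param A,B [node_set()]s or character vectors; members outside the
#'   network are ignored.
#' @return integer pair count.
#' @export
set_connectivity <- function(net, A, B) {
  ab <- disjoint_pair(net, A, B)
  M <- igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
  sub <- M[ab$A, ab$B, drop = FALSE] + Matrix::t(M[ab$B, ab$A, drop = FALSE])
  sum(sub > 0)
}

#' Shortest-path distance between two metabolite sets
#'
#' For every cross pair the distance is the smaller of the two directed
#' shortest-path lengths, `min(d(a -> b), d(b -> a))`. Returns the mean
#' over pairs with a finite distance and the coverage (fraction of cross
#' pairs connected at all).
#'
#' @inheritParams set_connectivity
#' @return list with `distance` (mean, `>= 1`), `coverage` in `[0, 1]`
#'   and `n_pairs`.
#' @export
set_distance <- function(net, A, B) {
  ab <- disjoint_pair(net, A, B)
  D <- cross_distances(net, ab$A, ab$B)
  fin <- is.finite(D)
  if (!any(fin)) stop("sets mutually unreachable")
  list(distance = mean(D[fin]), coverage = mean(fin), n_pairs = length(D))
}

disjoint_pair <- function(net, A, B) {
  nodes <- net_nodes(net)
  A <- intersect(set_members(A), nodes)
  B <- intersect(set_members(B), nodes)
  if (!length(A) || !length(B)) stop("A and B must be nonempty in the network")
  shared <- intersect(A, B)
  A2 <- setdiff(A, shared)
  B2 <- setdiff(B, shared)
  if (!length(A2) || !length(B2)) stop("sets coincide")
  list(A = A2, B = B2)
}

# |A| x |B| matrix of min-direction shortest-path lengths
cross_distances <- function(net, A, B) {
  g <- net$graph
  Dab <- igraph::distances(g, v = A, to = B, mode = "out")
  Dba <- t(igraph::distances(g, v = B, to = A, mode = "out"))
  pmin(Dab, Dba)
}

#' Proximity of a metabolite set to a target set, with random-set nulls
#'
#' Computes the observed connectivity and mean min-direction distance
#' between `A` and `B`, then standardises both against `R` random sets of
#' `|A|` nodes drawn uniformly from the network (the target `B` stays
#' fixed). A set proximal to `B` shows `z_connectivity > 0` and
#' `z_distance < 0`. Shared members are removed pairwise before each
#' evaluation, so the measures reflect between-set structure.
#'
#' @inheritParams set_connectivity
#' @param R replicates for the nulls.
#' @param seed integer seed.
#' @return object of class `proximity`: list with `connectivity`,
#'   `connectivity_rate` (per possible cross pair), `distance`,
#'   `coverage`, `z_connectivity`, `z_distance`, the two
#'   [null_distribution()]s (`null_connectivity`, `null_distance`) and
#'   `seed`.
#' @export
proximity <- function(net, A, B, R = 1e3, seed = 1L) {
  ab <- disjoint_pair(net, A, B)
  obs_conn <- set_connectivity(net, A, B)
  obs_dist <- set_distance(net, A, B)
  a_size <- length(intersect(set_members(A), net_nodes(net)))

  # precompute adjacency indicators and min-direction distances to B once;
  # the per-replicate statistics are then pure matrix lookups
  nodes <- net_nodes(net)
  Bm <- ab$B
  M <- igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
  adjB <- (M[, Bm, drop = FALSE] + Matrix::t(M[Bm, , drop = FALSE])) > 0
  DB <- cross_distances(net, nodes, Bm)
  rownames(adjB) <- nodes
  rownames(DB) <- nodes
  Ball <- set_members(B)

  conn_stat <- function(net, set) {
    A2 <- setdiff(set, Ball)
    B2 <- setdiff(Bm, set)
    if (!length(A2) || !length(B2)) return(NA_real_)
    sum(adjB[A2, B2, drop = FALSE])
  }
  dist_stat <- function(net, set) {
    A2 <- setdiff(set, Ball)
    B2 <- setdiff(Bm, set)
    if (!length(A2) || !length(B2)) return(NA_real_)
    d <- DB[A2, B2, drop = FALSE]
    fin <- is.finite(d)
    if (!any(fin)) return(NA_real_)
    mean(d[fin])
  }
  null_conn <- null_distribution(net, a_size, conn_stat, R, seed = seed,
                                 statistic_name = "connectivity")
  null_dist <- null_distribution(net, a_size, dist_stat, R, seed = seed + 1L,
                                 statistic_name = "distance")
  structure(list(connectivity = obs_conn,
                 connectivity_rate = obs_conn / (length(ab$A) * length(ab$B)),
                 distance = obs_dist$distance,
                 coverage = obs_dist$coverage,
                 z_connectivity = z_score(obs_conn, null_conn)$z,
                 z_distance = z_score(obs_dist$distance, null_dist)$z,
                 null_connectivity = null_conn,
                 null_distance = null_dist,
                 seed = as.integer(seed)),
            class = "proximity")
}

#' @export
print.proximity <- function(x, ...) {
  cat(sprintf("Set proximity: connectivity %d (rate %.4f, Z = %.2f); mean distance %.3f over %.0f%% of pairs (Z = %.2f)\n",
              x$connectivity, x$connectivity_rate, x$z_connectivity,
              x$distance, 100 * x$coverage, x$z_distance))
  sig <- abs(c(x$z_connectivity, x$z_distance)) > 2.33
  cat("  |Z| > 2.33:", paste(c("connectivity", "distance")[sig],
                             collapse = ", "),
      if (!any(sig)) "none", "\n")
  invisible(x)
}

#' @export
plot.proximity <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$null_connectivity, observed = x$connectivity)
  plot(x$null_distance, observed = x$distance)
  invisible(x)
}

#' Simplified inter-set subnetwork
#'
#' Induced subgraph on `A`, `B` and every node lying on a directed path
#' of length at most `max_len` between a member of `A` and a member of
#' `B` (in either direction). Node roles are recorded in the result's
#' graph as a vertex attribute `role` with values `"A"`, `"B"`,
#' `"both"`, `"linker"`.
#'
#' @inheritParams set_connectivity
#' @param max_len maximum path length (`>= 1`).
#' @return a [metabolic_network()]; empty (with a warning) when neither
#'   set is present.
#' @export
simplified_subnet <- function(net, A, B, max_len = 2L) {
  stopifnot(inherits(net, "metabolic_network"), max_len >= 1L)
  nodes <- net_nodes(net)
  Am <- intersect(set_members(A), nodes)
  Bm <- intersect(set_members(B), nodes)
  g <- net$graph
  linkers <- character()
  if (length(Am) && length(Bm)) {
    dA_out <- suppressWarnings(igraph::distances(g, v = Am, mode = "out"))
    dB_in <- suppressWarnings(igraph::distances(g, v = Bm, mode = "out"))
    # x on an a->x->b path: min_a d(a,x) + min_b d(x,b) <= max_len
    a_to <- apply(dA_out, 2L, min)     # min over a of d(a, x)
    to_b <- apply(dB_in, 2L, min)      # min over b of d(b, x) i.e. b -> x
    fwd <- a_to + apply(suppressWarnings(
      igraph::distances(g, v = Bm, mode = "in")), 2L, min)
    bwd <- to_b + apply(suppressWarnings(
      igraph::distances(g, v = Am, mode = "in")), 2L, min)
    on_path <- pmin(fwd, bwd) <= max_len
    linkers <- setdiff(nodes[on_path], c(Am, Bm))
  }
  keep <- unique(c(Am, Bm, linkers))
  if (!length(keep)) {
    warning("no members of A or B in the network; returning empty subnetwork")
    return(structure(list(graph = igraph::make_empty_graph(directed = TRUE),
                          compound_pathways = list(),
                          pathway_category = character()),
                     class = "metabolic_network"))
  }
  sub <- induced_subnetwork(net, keep)
  nm <- net_nodes(sub)
  role <- ifelse(nm %in% intersect(Am, Bm), "both",
          ifelse(nm %in% Am, "A",
          ifelse(nm %in% Bm, "B", "linker")))
  igraph::V(sub$graph)$role <- role
  sub
}
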