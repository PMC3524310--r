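#' Node degrees of the directed network
#'
#' @param net a [metabolic_network()].
#' @return data.frame with columns `node`, `in_degree`, `out_degree`.
#'   Both columns have mean `|arcs|/|nodes|`.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  g <- net$graph
  data.frame(node = igraph::V(g)$name,
             in_degree = as.integer(igraph::degree(g, mode = "in")),
             out_degree = as.integer(igraph::degree(g, mode = "out")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reachability-weighted closeness centrality
#'
#' The background network is not strongly connected, so classic closeness
#' (which requires every pair to be reachable) is undefined. The form used
#' here weights efficiency by coverage: with `r_v` the number of other
#' nodes reachable from `v` (direction `"out"`) or reaching `v`
#' (direction `"in"`) and `S_v` the sum of those shortest-path lengths,
#'
#'   closeness(v) = (r_v / (n - 1)) * (r_v / S_v).
#'
#' Nodes reaching nothing score 0. On a strongly connected graph
#' `r_v = n - 1` and this reduces to classic closeness.
#'
#' @param net a [metabolic_network()]; needs at least 2 nodes.
#' @param direction `"out"` (paths from the node) or `"in"` (paths to it).
#' @return named numeric vector of values in `[0, 1]`.
#' @export
node_closeness <- function(net, direction = c("out", "in")) {
  stopifnot(inherits(net, "metabolic_network"))
  direction <- match.arg(direction)
  g <- net$graph
  n <- igraph::vcount(g)
  if (n < 2L) stop("closeness needs at least 2 nodes")
  D <- igraph::distances(g, mode = direction)
  diag(D) <- Inf
  fin <- is.finite(D)
  r <- rowSums(fin)
  S <- rowSums(D * fin, na.rm = TRUE)  # Inf * FALSE -> NaN, dropped by na.rm
  out <- ifelse(r > 0, (r / (n - 1)) * (r / S), 0)
  stats::setNames(out, igraph::V(g)$name)
}

#' Directed shortest-path betweenness
#'
#' Standard betweenness on the digraph with unit arc weights, endpoints
#' excluded, normalized by `(n - 1)(n - 2)` ordered pairs (the graph is
#' directed, so the count is not halved).
#'
#' @param net a [metabolic_network()]; needs at least 3 nodes.
#' @return named numeric vector of values in `[0, 1]`.
#' @export
node_betweenness <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  if (n < 3L) stop("betweenness needs at least 3 nodes")
  b <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  stats::setNames(b / ((n - 1) * (n - 2)), igraph::V(g)$name)
}

#' Full centrality table
#'
#' @param net a [metabolic_network()] with at least 3 nodes.
#' @return data.frame of class `centrality_table`: `node`, `in_degree`,
#'   `out_degree`, `closeness_in`, `closeness_out`, `betweenness`.
#' @export
centrality_table <- function(net) {
  deg <- node_degrees(net)
  deg$closeness_in <- unname(node_closeness(net, "in")[deg$node])
  deg$closeness_out <- unname(node_closeness(net, "out")[deg$node])
  deg$betweenness <- unname(node_betweenness(net)[deg$node])
  class(deg) <- c("centrality_table", "data.frame")
  deg
}

#' Centrality means over a metabolite set
#'
#' Averages each centrality column over the members of `set` found in the
#' table (members absent from the network are skipped and counted).
#'
#' @param table a [centrality_table()] (or any data.frame with a `node`
#'   column and numeric centrality columns).
#' @param set a [node_set()] or character vector of compound ids.
#' @return object of class `set_summary`: list with `n_found`, `n_set`,
#'   and `means` (named numeric).
#' @export
set_summary <- function(table, set) {
  members <- set_members(set)
  found <- intersect(members, table$node)
  if (!length(found)) stop("set disjoint from network")
  rows <- table[match(found, table$node), setdiff(names(table), "node"),
                drop = FALSE]
  structure(list(n_found = length(found), n_set = length(members),
                 means = colMeans(rows)),
            class = "set_summary")
}

#' @export
print.set_summary <- function(x, ...) {
  cat("Set summary over", x$n_found, "of", x$n_set, "members in network\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Export a centrality table as TSV
#'
#' @param table a [centrality_table()].
#' @param path file path.
#' @export
write_centralities <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
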