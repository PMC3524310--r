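#' Construct a metabolic network object
#'
#' A `metabolic_network` is a directed simple graph over compound ids
#' (no self-loops, no parallel arcs) together with two annotation maps:
#' compound -> pathway ids and pathway id -> biological-process category.
#' Most users build one from a parsed reaction list with [build_network()];
#' this constructor accepts an explicit arc table and is the programmatic
#' entry point used by the synthetic generator and the tests.
#'
#' @param arcs two-column data.frame (or matrix) of compound ids,
#'   `from` and `to`. Self-loops are dropped and duplicate arcs collapsed.
#' @param compound_pathways named list mapping compound id to a character
#'   vector of pathway ids, or a two-column data.frame
#'   (compound, pathway). May cover compounds absent from the graph.
#' @param pathway_category named character vector mapping pathway id to a
#'   category label, or a two-column data.frame (pathway, category).
#' @return object of class `metabolic_network` with elements `graph`
#'   (a directed [igraph::igraph]), `compound_pathways`, `pathway_category`.
#' @export
metabolic_network <- function(arcs, compound_pathways = list(),
                              pathway_category = character()) {
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (ncol(arcs) < 2L) stop("'arcs' must have two columns (from, to)")
  names(arcs)[1:2] <- c("from", "to")
  arcs$from <- as.character(arcs$from)
  arcs$to <- as.character(arcs$to)
  arcs <- arcs[arcs$from != arcs$to, c("from", "to"), drop = FALSE]
  arcs <- unique(arcs)
  if (nrow(arcs) == 0L) stop("empty network")
  g <- igraph::graph_from_data_frame(arcs, directed = TRUE)
  new_metabolic_network(g,
                        normalize_compound_pathways(compound_pathways),
                        normalize_pathway_category(pathway_category))
}

new_metabolic_network <- function(graph, compound_pathways, pathway_category) {
  structure(list(graph = graph,
                 compound_pathways = compound_pathways,
                 pathway_category = pathway_category),
            class = "metabolic_network")
}

normalize_compound_pathways <- function(x) {
  if (is.data.frame(x)) {
    x <- split(as.character(x[[2L]]), as.character(x[[1L]]))
  }
  if (length(x) == 0L) return(structure(list(), names = character()))
  lapply(x, function(p) unique(as.character(p)))
}

normalize_pathway_category <- function(x) {
  if (is.data.frame(x)) {
    x <- stats::setNames(as.character(x[[2L]]), as.character(x[[1L]]))
  }
  if (length(x) == 0L) return(stats::setNames(character(), character()))
  stats::setNames(as.character(x), names(x))
}

#' Nodes and arcs of a metabolic network
#'
#' @param net a [metabolic_network()].
#' @return `net_nodes()`: character vector of compound ids; `net_arcs()`:
#'   data.frame with columns `from`, `to`.
#' @export
net_nodes <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  igraph::V(net$graph)$name
}

#' @rdname net_nodes
#' @export
net_arcs <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE)
}

n_nodes <- function(net) igraph::vcount(net$graph)
n_arcs <- function(net) igraph::ecount(net$graph)

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network:", n_nodes(x), "compounds,", n_arcs(x), "arcs",
      "(mean degree", sprintf("%.2f", n_arcs(x) / n_nodes(x)), "in each direction)\n")
  ann <- sum(names(x$compound_pathways) %in% net_nodes(x))
  cat("  pathway-annotated compounds in network:", ann, "/", n_nodes(x), "\n")
  cat("  pathways with category labels:", length(x$pathway_category), "\n")
  invisible(x)
}

#' @export
summary.metabolic_network <- function(object, ...) {
  bt <- bow_tie(object)
  out <- list(nodes = n_nodes(object), arcs = n_arcs(object),
              mean_degree = n_arcs(object) / n_nodes(object),
              gsc = length(bt$gsc), isolated = length(bt$isolated))
  class(out) <- "summary.metabolic_network"
  out
}

#' @export
print.summary.metabolic_network <- function(x, ...) {
  cat("Nodes:", x$nodes, " Arcs:", x$arcs,
      " Mean in/out degree:", sprintf("%.3f", x$mean_degree), "\n")
  cat("Giant strong component:", x$gsc, "nodes;",
      x$isolated, "nodes in isolated components\n")
  invisible(x)
}

#' Induced subnetwork on a node subset
#'
#' Keeps the arcs among `nodes` and restricts the annotations; annotation
#' maps are carried over unchanged for the retained compounds.
#'
#' @param net a [metabolic_network()].
#' @param nodes character vector of compound ids (unknown ids ignored).
#' @return a [metabolic_network()].
#' @export
induced_subnetwork <- function(net, nodes) {
  stopifnot(inherits(net, "metabolic_network"))
  keep <- intersect(net_nodes(net), nodes)
  g <- igraph::induced_subgraph(net$graph, keep)
  new_metabolic_network(g, net$compound_pathways, net$pathway_category)
}

#' Metabolite sets with optional regulation
#'
#' A `node_set` is a named set of compound ids with optional per-member
#' regulation (+1 up-regulated, -1 down-regulated in the case group).
#'
#' @param compounds character vector of compound ids (deduplicated).
#' @param regulation optional integer vector of +1/-1, recycled checked
#'   against `compounds`.
#' @param name optional label for the set.
#' @return data.frame of class `node_set` with columns `compound` and
#'   `regulation` (NA when unmeasured).
#' @export
node_set <- function(compounds, regulation = NULL, name = NULL) {
  compounds <- as.character(compounds)
  keep <- !duplicated(compounds)
  compounds <- compounds[keep]
  if (is.null(regulation)) {
    regulation <- rep(NA_integer_, length(compounds))
  } else {
    regulation <- as.integer(regulation)[keep]
    if (length(regulation) != length(compounds))
      stop("'regulation' must have one entry per compound")
    if (!all(is.na(regulation) | regulation %in% c(-1L, 1L)))
      stop("regulation entries must be +1, -1 or NA")
  }
  out <- data.frame(compound = compounds, regulation = regulation,
                    stringsAsFactors = FALSE)
  attr(out, "set_name") <- name
  class(out) <- c("node_set", "data.frame")
  out
}

as_node_set <- function(x) {
  if (inherits(x, "node_set")) return(x)
  if (is.data.frame(x)) {
    return(node_set(x[[1L]], if (ncol(x) >= 2L) x[[2L]] else NULL))
  }
  node_set(x)
}

set_members <- function(x) as_node_set(x)$compound

#' Read / write a metabolite-set TSV
#'
#' The file has one compound id per line with an optional second column of
#' +1/-1 regulation; lines starting with `#` are comments. A header line
#' `compound<TAB>regulation` is written and tolerated on input.
#'
#' @param path file path.
#' @param x a [node_set()] (or coercible).
#' @return `read_node_set()`: a [node_set()].
#' @export
read_node_set <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) && grepl("^compound\\b", lines[1L])) lines <- lines[-1L]
  if (!length(lines)) stop("empty metabolite-set file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  comp <- vapply(parts, `[[`, "", 1L)
  reg <- vapply(parts, function(p)
    if (length(p) >= 2L && nzchar(p[2L]) && p[2L] != "NA")
      as.integer(p[2L]) else NA_integer_,
    integer(1L))
  node_set(comp, if (all(is.na(reg))) NULL else reg)
}

#' @rdname read_node_set
#' @export
write_node_set <- function(x, path) {
  x <- as_node_set(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
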