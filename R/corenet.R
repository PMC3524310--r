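#' Assemble the core subnetwork of a differential metabolite set
#'
#' Takes the union of the induced subgraphs of the enriched pathways,
#' prunes it to nodes within undirected distance `radius` of some
#' differential member (distances measured inside the pathway union;
#' `radius = Inf` keeps the whole pathways), and attaches per-node
#' regulation and pathway attributes. Non-differential nodes left without
#' any arc after pruning are dropped; differential members are always
#' retained.
#'
#' @param net a [metabolic_network()] with pathway annotations.
#' @param enriched character vector of enriched pathway ids.
#' @param diff a [node_set()] with regulation (+1/-1; NA allowed).
#' @param radius nonnegative pruning radius (default 2; `Inf` disables
#'   pruning).
#' @return object of class `core_network`: list with `network` (a
#'   [metabolic_network()] restricted to the core), `attributes`
#'   (data.frame: `compound`, `regulation` in up/down/unmeasured,
#'   `differential`, `pathways`, `roles`).
#' @export
build_core <- function(net, enriched, diff, radius = 2) {
  stopifnot(inherits(net, "metabolic_network"))
  if (!length(enriched)) stop("need at least one enriched pathway")
  if (radius < 0) stop("radius must be nonnegative")
  diff <- as_node_set(diff)
  cp <- net$compound_pathways
  in_enriched <- vapply(cp, function(p) any(p %in% enriched), logical(1L))
  pool <- intersect(names(cp)[in_enriched], net_nodes(net))
  if (!length(pool)) stop("no network compound annotated to an enriched pathway")
  diff_in <- intersect(diff$compound, pool)
  if (!length(diff_in))
    stop("no differential member in any enriched pathway")

  sub <- induced_subnetwork(net, pool)
  keep <- pool
  if (is.finite(radius)) {
    d <- igraph::distances(sub$graph, v = diff_in, mode = "all")
    reach <- apply(d, 2L, min) <= radius
    keep <- net_nodes(sub)[reach]
  }
  core <- induced_subnetwork(net, keep)
  deg <- igraph::degree(core$graph, mode = "all")
  drop <- names(deg)[deg == 0L & !(names(deg) %in% diff_in)]
  if (length(drop)) core <- induced_subnetwork(core, setdiff(keep, drop))
  nm <- net_nodes(core)

  reg_code <- diff$regulation[match(nm, diff$compound)]
  regulation <- ifelse(is.na(match(nm, diff$compound)), "unmeasured",
                ifelse(is.na(reg_code), "unmeasured",
                ifelse(reg_code > 0, "up", "down")))
  pw <- vapply(nm, function(v)
    paste(intersect(cp[[v]], enriched), collapse = "|"), "")
  attrs <- data.frame(compound = nm, regulation = regulation,
                      differential = nm %in% diff$compound,
                      pathways = unname(pw), roles = "",
                      stringsAsFactors = FALSE)
  structure(list(network = core, attributes = attrs,
                 enriched = enriched, radius = radius),
            class = "core_network")
}

#' Tag core-network compounds with functional roles
#'
#' Applies user-supplied role lists (e.g. neurotransmitters, neuroactive
#' metabolites) as node tags; a compound appearing in several lists keeps
#' all tags. Ids absent from the core are ignored with a warning.
#'
#' @param core a [build_core()] result.
#' @param role_lists named list, role label -> character vector of
#'   compound ids.
#' @return the `core_network` with updated `roles` (|-separated tags).
#' @export
annotate_roles <- function(core, role_lists) {
  stopifnot(inherits(core, "core_network"))
  if (!length(role_lists)) return(core)
  if (is.null(names(role_lists)) || any(!nzchar(names(role_lists))))
    stop("role_lists must be a named list")
  attrs <- core$attributes
  unknown <- character()
  for (role in names(role_lists)) {
    ids <- as.character(role_lists[[role]])
    hit <- attrs$compound %in% ids
    unknown <- c(unknown, setdiff(ids, attrs$compound))
    attrs$roles[hit] <- ifelse(nzchar(attrs$roles[hit]),
                               paste(attrs$roles[hit], role, sep = "|"), role)
  }
  if (length(unknown))
    warning("role ids not in core network, ignored: ",
            paste(unique(unknown), collapse = ", "))
  core$attributes <- attrs
  core
}

#' @export
print.core_network <- function(x, ...) {
  a <- x$attributes
  cat(sprintf("Core network: %d compounds (%d differential), %d arcs, %d enriched pathway(s), radius %s\n",
              nrow(a), sum(a$differential), n_arcs(x$network),
              length(x$enriched), format(x$radius)))
  invisible(x)
}

#' @export
summary.core_network <- function(object, ...) {
  a <- object$attributes
  tagged <- sum(nzchar(a$roles))
  cat(sprintf("Core network of %d compounds including %d differential metabolites\n",
              nrow(a), sum(a$differential)))
  cat(sprintf("  regulation: %d up, %d down, %d unmeasured\n",
              sum(a$regulation == "up"), sum(a$regulation == "down"),
              sum(a$regulation == "unmeasured")))
  cat(sprintf("  role-tagged compounds: %d among %d\n", tagged, nrow(a)))
  if (tagged) {
    tags <- unlist(strsplit(a$roles[nzchar(a$roles)], "|", fixed = TRUE))
    tab <- table(tags)
    for (t in names(tab)) cat(sprintf("    %s: %d\n", t, tab[[t]]))
  }
  invisible(object)
}

#' Export a core network with its node attributes
#'
#' Writes the graph (GraphML with `regulation`, `pathways` and `roles`
#' vertex attributes, or SIF) and, alongside SIF, a node-attribute TSV
#' for graph viewers.
#'
#' @param core a [build_core()] result.
#' @param path output file path (for SIF, a `<path>.attrs.tsv` companion
#'   is written).
#' @param format `"graphml"` or `"sif"`.
#' @export
write_core <- function(core, path, format = c("graphml", "sif")) {
  stopifnot(inherits(core, "core_network"))
  format <- match.arg(format)
  a <- core$attributes
  if (format == "graphml") {
    net <- core$network
    g <- net$graph
    idx <- match(igraph::V(g)$name, a$compound)
    igraph::V(g)$regulation <- a$regulation[idx]
    igraph::V(g)$pathways <- a$pathways[idx]
    igraph::V(g)$roles <- a$roles[idx]
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_network(core$network, path, format = "sif")
    utils::write.table(a, paste0(path, ".attrs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
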