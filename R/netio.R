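#' Default currency-metabolite list
#'
#' Ubiquitous cofactor-like compounds (water, ATP, NAD and friends) act as
#' shortcuts connecting otherwise unrelated reactions, so they are removed
#' before the substrate-product graph is built. Real analyses should pass a
#' curated list; this default names the tokens used by the synthetic
#' KEGG-like dialect shipped with the package.
#'
#' @return character vector of compound ids.
#' @export
default_currency <- function() {
  c("H2O", "ATP", "ADP", "NAD", "NADH", "NADP", "NADPH",
    "CO2", "PI", "PPI", "COA", "H")
}

#' Parse a KEGG-style reaction list
#'
#' Reads a line-oriented reaction file in the
#' `reaction_mapformula.lst` dialect: each data line is
#' `RID: PID: lhs <arrow> rhs` where the arrow is one of `=>`, `<=`,
#' `<=>` and each side is a `+`-separated list of compound ids.
#' Lines starting with `#` and blank lines are skipped. Compounds in
#' `currency` are removed from both sides; reactions whose substrate or
#' product side becomes empty are dropped (they no longer connect two
#' non-currency compounds).
#'
#' @param x path to a reaction-list file, or a character vector of lines.
#' @param currency character vector of currency compound ids to remove
#'   (default none; see [default_currency()]).
#' @return data.frame of class `reaction_list` with columns
#'   `reaction_id`, `pathway_id`, `direction`
#'   (`"forward"`, `"reverse"` or `"bidirectional"`) and list-columns
#'   `substrates`, `products`. `<=` lines keep their sides as written and
#'   get `direction = "reverse"`.
#' @export
parse_reaction_list <- function(x, currency = character()) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("reaction list contains no data lines")

  m <- regexec("^\\s*([^:\\s]+):\\s*([^:\\s]+):\\s*(.*\\S)\\s*$", lines)
  hits <- regmatches(lines, m)
  bad <- which(lengths(hits) != 4L)
  if (length(bad))
    stop("malformed reaction line ", lineno[bad[1L]], ": ", lines[bad[1L]])

  parse_one <- function(h, ln) {
    eq <- h[4L]
    arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>"
      else if (grepl("=>", eq, fixed = TRUE)) "=>"
      else if (grepl("<=", eq, fixed = TRUE)) "<="
      else stop("unknown reaction arrow on line ", ln, ": ", eq)
    sides <- strsplit(eq, arrow, fixed = TRUE)[[1L]]
    if (length(sides) != 2L)
      stop("malformed equation on line ", ln, ": ", eq)
    split_side <- function(s) {
      toks <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
      toks <- toks[nzchar(toks)]
      if (!length(toks)) stop("empty reaction side on line ", ln)
      toks
    }
    list(substrates = split_side(sides[1L]),
         products = split_side(sides[2L]),
         direction = switch(arrow, "=>" = "forward", "<=" = "reverse",
                            "<=>" = "bidirectional"))
  }
  parsed <- Map(parse_one, hits, lineno)

  out <- data.frame(
    reaction_id = vapply(hits, `[[`, "", 2L),
    pathway_id = vapply(hits, `[[`, "", 3L),
    direction = vapply(parsed, `[[`, "", "direction"),
    stringsAsFactors = FALSE)
  out$substrates <- lapply(parsed, function(p) setdiff(p$substrates, currency))
  out$products <- lapply(parsed, function(p) setdiff(p$products, currency))

  nonempty <- lengths(out$substrates) > 0L & lengths(out$products) > 0L
  out <- out[nonempty, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reaction_list", "data.frame")
  out
}

#' Build the directed compound network from parsed reactions
#'
#' Every reaction is expanded into its full substrate x product arc set:
#' forward reactions add an arc s -> p for each substrate s and product p,
#' reverse reactions add p -> s, and bidirectional reactions add both.
#' Self-loops are discarded and parallel arcs collapsed, so the result is a
#' simple digraph; its node set is the union of arc endpoints.
#'
#' @param records a `reaction_list` from [parse_reaction_list()].
#' @param compound_pathways,pathway_category annotation maps, see
#'   [metabolic_network()]; typically from [read_annotations()] and
#'   [read_categories()].
#' @return a [metabolic_network()].
#' @export
build_network <- function(records, compound_pathways = list(),
                          pathway_category = character()) {
  if (is.null(records) || nrow(records) == 0L) stop("empty network")
  arcs_of <- function(subs, prods, dir) {
    pairs <- expand.grid(from = subs, to = prods,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    switch(dir,
           forward = pairs,
           reverse = data.frame(from = pairs$to, to = pairs$from,
                                stringsAsFactors = FALSE),
           bidirectional = rbind(pairs,
                                 data.frame(from = pairs$to, to = pairs$from,
                                            stringsAsFactors = FALSE)))
  }
  arcs <- do.call(rbind, Map(arcs_of, records$substrates, records$products,
                             records$direction))
  arcs <- unique(arcs[arcs$from != arcs$to, , drop = FALSE])
  if (nrow(arcs) == 0L) stop("empty network")
  metabolic_network(arcs, compound_pathways, pathway_category)
}

#' Read annotation tables
#'
#' `read_annotations()` reads a two-column TSV `compound_id<TAB>pathway_id`
#' (a compound may appear on several lines); `read_categories()` reads
#' `pathway_id<TAB>category`. `#` comment lines and an optional header are
#' skipped.
#'
#' @param path file path.
#' @return `read_annotations()`: named list compound -> pathway ids;
#'   `read_categories()`: named character pathway -> category.
#' @export
read_annotations <- function(path) {
  df <- read_two_col_tsv(path, c("compound", "pathway"))
  normalize_compound_pathways(df)
}

#' @rdname read_annotations
#' @export
read_categories <- function(path) {
  df <- read_two_col_tsv(path, c("pathway", "category"))
  normalize_pathway_category(df)
}

read_two_col_tsv <- function(path, cols) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) && grepl(paste0("^", cols[1L], "\\b"), lines[1L]))
    lines <- lines[-1L]
  if (!length(lines)) stop("no data rows in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("expected two tab-separated columns in ", path)
  stats::setNames(data.frame(vapply(parts, `[[`, "", 1L),
                             vapply(parts, `[[`, "", 2L),
                             stringsAsFactors = FALSE), cols)
}

#' Bow-tie decomposition of a directed network
#'
#' Partitions the nodes into the giant strongly connected component (GSC),
#' the IN set (reaches the GSC), the OUT set (reachable from the GSC),
#' tendrils (weakly but not directionally connected to the GSC) and the
#' isolated subset (weak components not containing the GSC). When several
#' strongly connected components tie for the largest size, the one whose
#' lexicographically smallest member id is smallest is taken as the GSC.
#'
#' @param net a [metabolic_network()].
#' @return object of class `bow_tie`: list of character vectors `gsc`,
#'   `in_set`, `out_set`, `tendrils`, `isolated`.
#' @export
bow_tie <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  g <- net$graph
  nm <- igraph::V(g)$name
  sc <- igraph::components(g, mode = "strong")
  sizes <- sc$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    smallest <- vapply(cand, function(ci) min(nm[sc$membership == ci]), "")
    cand <- cand[order(smallest)][1L]
  }
  gsc_id <- cand[1L]
  gsc <- nm[sc$membership == gsc_id]
  g0 <- gsc[1L]

  d_to_gsc <- igraph::distances(g, v = igraph::V(g), to = g0, mode = "out")[, 1L]
  d_from_gsc <- igraph::distances(g, v = g0, to = igraph::V(g), mode = "out")[1L, ]
  reaches <- is.finite(d_to_gsc)
  reached <- is.finite(d_from_gsc)
  wc <- igraph::components(g, mode = "weak")
  gsc_weak <- wc$membership[match(g0, nm)]
  in_gsc <- nm %in% gsc

  in_set <- nm[reaches & !reached & !in_gsc]
  out_set <- nm[reached & !reaches & !in_gsc]
  isolated <- nm[wc$membership != gsc_weak]
  tendrils <- setdiff(nm, c(gsc, in_set, out_set, isolated))
  structure(list(gsc = gsc, in_set = in_set, out_set = out_set,
                 tendrils = tendrils, isolated = isolated),
            class = "bow_tie")
}

#' @export
print.bow_tie <- function(x, ...) {
  cat("Bow-tie decomposition:\n")
  for (nmv in names(x)) cat(sprintf("  %-8s %d nodes\n", nmv, length(x[[nmv]])))
  invisible(x)
}

#' Remove the isolated subset of the bow-tie structure
#'
#' Returns the most connected part of the network (GSC, IN, OUT and
#' tendrils), the part used for module decomposition.
#'
#' @param net a [metabolic_network()].
#' @return a [metabolic_network()] without the isolated components.
#' @export
remove_isolated <- function(net) {
  bt <- bow_tie(net)
  induced_subnetwork(net, setdiff(net_nodes(net), bt$isolated))
}

#' Write / read a network in standard graph formats
#'
#' GraphML round-trips nodes, arcs and both annotation maps (pathway
#' membership is stored per node, the pathway -> category map as a graph
#' attribute). SIF writes one `from<TAB>rxn<TAB>to` line per arc.
#' The edge-list TSV has a `from`/`to` header line.
#'
#' @param net a [metabolic_network()].
#' @param path file path.
#' @param format one of `"graphml"`, `"sif"`, `"edgelist"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a [metabolic_network()] (without annotations for SIF and
#'   edge-list input).
#' @export
write_network <- function(net, path, format = c("graphml", "sif", "edgelist")) {
  stopifnot(inherits(net, "metabolic_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- net$graph
    nm <- igraph::V(g)$name
    pw <- vapply(nm, function(v) {
      p <- net$compound_pathways[[v]]
      if (is.null(p)) "" else paste(sort(p), collapse = "|")
    }, "")
    igraph::V(g)$pathways <- unname(pw)
    pc <- net$pathway_category
    g <- igraph::set_graph_attr(g, "pathway_category",
      if (length(pc)) paste(names(pc), pc, sep = "=", collapse = "|") else "")
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    el <- net_arcs(net)
    writeLines(paste(el$from, "rxn", el$to, sep = "\t"), path)
  } else {
    el <- net_arcs(net)
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("graphml", "sif", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nm <- igraph::V(g)$name
    cp <- list()
    if ("pathways" %in% igraph::vertex_attr_names(g)) {
      pw <- igraph::V(g)$pathways
      nonz <- nzchar(pw)
      cp <- stats::setNames(strsplit(pw[nonz], "|", fixed = TRUE), nm[nonz])
      g <- igraph::delete_vertex_attr(g, "pathways")
    }
    pc <- stats::setNames(character(), character())
    if ("pathway_category" %in% igraph::graph_attr_names(g)) {
      enc <- igraph::graph_attr(g, "pathway_category")
      if (nzchar(enc)) {
        kv <- strsplit(strsplit(enc, "|", fixed = TRUE)[[1L]], "=", fixed = TRUE)
        pc <- stats::setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
      }
      g <- igraph::delete_graph_attr(g, "pathway_category")
    }
    new_metabolic_network(g, cp, pc)
  } else if (format == "sif") {
    parts <- strsplit(readLines(path), "\t", fixed = TRUE)
    parts <- parts[lengths(parts) >= 3L]
    if (!length(parts)) stop("no interactions in SIF file ", path)
    metabolic_network(data.frame(from = vapply(parts, `[[`, "", 1L),
                                 to = vapply(parts, `[[`, "", 3L),
                                 stringsAsFactors = FALSE))
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character")
    metabolic_network(df)
  }
}
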