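#' Configuration for the synthetic KEGG-like generator
#'
#' The generator emulates the structure of a currency-filtered human
#' metabolic network at desk scale: a few internally dense pathways that
#' are sparsely cross-linked (so pathways align with topological modules),
#' a handful of currency metabolites appearing in reactions across all
#' pathways, a giant strongly connected core encouraged by a substantial
#' reversible-reaction fraction, and small isolated components. Defaults
#' were chosen once so that the currency-filtered network has a mean
#' in/out degree near 1.5, the density regime of the genome-scale
#' compound network this emulates.
#'
#' @param n_pathways number of pathways.
#' @param compounds_per_pathway compounds generated per pathway.
#' @param intra_pathway_reactions reactions sampled within each pathway.
#' @param cross_pathway_reactions reactions linking two pathways (total).
#' @param currency_count number of currency metabolites woven through
#'   reactions of every pathway.
#' @param bidirectional_fraction probability that a reaction is reversible.
#' @param isolated_component_count number of two-compound components kept
#'   disconnected from the pathway part (they form the isolated subset of
#'   the bow-tie structure and are annotated to no pathway).
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `synth_config` (a named list).
#' @export
synth_config <- function(n_pathways = 5L,
                         compounds_per_pathway = 20L,
                         intra_pathway_reactions = 9L,
                         cross_pathway_reactions = 8L,
                         currency_count = 4L,
                         bidirectional_fraction = 0.3,
                         isolated_component_count = 2L,
                         seed = 1L) {
  cfg <- list(n_pathways = as.integer(n_pathways),
              compounds_per_pathway = as.integer(compounds_per_pathway),
              intra_pathway_reactions = as.integer(intra_pathway_reactions),
              cross_pathway_reactions = as.integer(cross_pathway_reactions),
              currency_count = as.integer(currency_count),
              bidirectional_fraction = as.numeric(bidirectional_fraction),
              isolated_component_count = as.integer(isolated_component_count),
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_pathways", "compounds_per_pathway",
                         "intra_pathway_reactions", "cross_pathway_reactions",
                         "currency_count", "isolated_component_count")])
  if (any(counts < 0L)) stop("all counts must be >= 0")
  if (cfg$n_pathways < 1L || cfg$compounds_per_pathway < 4L)
    stop("need at least one pathway with at least 4 compounds")
  if (cfg$bidirectional_fraction < 0 || cfg$bidirectional_fraction > 1)
    stop("bidirectional_fraction must be in [0, 1]")
  class(cfg) <- "synth_config"
  cfg
}

synth_categories <- c("Amino Acid Metabolism", "Carbohydrate Metabolism",
                      "Lipid Metabolism", "Nucleotide Metabolism",
                      "Metabolism of Cofactors and Vitamins",
                      "Xenobiotics Biodegradation and Metabolism")

#' Generate synthetic KEGG-like pipeline inputs
#'
#' Emits a reaction list in the `RID: PID: eq` dialect consumed by
#' [parse_reaction_list()], the two annotation tables, and a ground-truth
#' record: the planted module structure (pathway membership), the pathway
#' designated for enrichment, a planted differential metabolite set
#' (over-represented in that pathway) and a planted proximal target set
#' sampled within directed distance 2 of the differential set. Output is
#' byte-deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @param dir optional directory; when given, writes `reactions.lst`,
#'   `compound_pathways.tsv`, `pathway_category.tsv`, `differential.tsv`,
#'   `target.tsv` and a `ground_truth.json` sidecar there.
#' @param hub_bias hub bias passed to [plant_differential()].
#' @return list with elements `reactions` (character lines),
#'   `compound_pathways`, `pathway_category` (data.frames), `currency`
#'   (character), `network` (the [metabolic_network()] rebuilt from the
#'   emitted text via the package's own parser) and `truth` (list with
#'   `planted_modules`, `planted_enriched_pathway`, `planted_differential`,
#'   `planted_target`).
#' @export
generate_synthetic <- function(config = synth_config(), dir = NULL,
                               hub_bias = 0) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    npw <- config$n_pathways
    cpp <- config$compounds_per_pathway
    pw_ids <- sprintf("%05d", seq_len(npw) * 10L)
    compounds <- lapply(seq_len(npw), function(i)
      sprintf("C%05d", (i - 1L) * cpp + seq_len(cpp)))
    cur_pool <- c(default_currency(), sprintf("CUR%02d", seq_len(50L)))
    currency <- cur_pool[seq_len(config$currency_count)]
    cats <- synth_categories[(seq_len(npw) - 1L) %% length(synth_categories) + 1L]

    lines <- character()
    rid <- 0L
    emit <- function(pid, subs, prods, direction) {
      rid <<- rid + 1L
      arrow <- switch(direction, forward = "=>", reverse = "<=",
                      bidirectional = "<=>")
      if (direction == "reverse") { tmp <- subs; subs <- prods; prods <- tmp }
      sprintf("R%05d: %s: %s %s %s", rid, pid,
              paste(subs, collapse = " + "), arrow,
              paste(prods, collapse = " + "))
    }
    draw_direction <- function() {
      if (stats::runif(1) < config$bidirectional_fraction) return("bidirectional")
      # occasional '<=' lines exercise the reverse-arrow dialect
      if (stats::runif(1) < 0.1) "reverse" else "forward"
    }
    # hub compounds: within a pathway, participation is Zipf-weighted so a
    # few metabolites recur across many reactions, giving the heavy-tailed
    # degree distribution characteristic of real compound networks
    zipf_w <- function(m) 1 / seq_len(m)^0.8
    for (i in seq_len(npw)) {
      pool <- compounds[[i]]
      w <- zipf_w(length(pool))
      for (r in seq_len(config$intra_pathway_reactions)) {
        k <- sample(2:4, 1L, prob = c(0.5, 0.35, 0.15))
        picked <- sample(pool, k, prob = w)
        ns <- sample(seq_len(k - 1L), 1L)
        subs <- picked[seq_len(ns)]
        prods <- picked[-seq_len(ns)]
        if (length(currency) && stats::runif(1) < 0.3) {
          cur <- sample(currency, 1L)
          if (stats::runif(1) < 0.5) subs <- c(subs, cur) else prods <- c(prods, cur)
        }
        lines <- c(lines, emit(pw_ids[i], subs, prods, draw_direction()))
      }
    }
    if (npw >= 2L) {
      # first cross links follow a random spanning tree over pathways so the
      # pathway part forms one weakly connected background network; the rest
      # are random pathway pairs
      ord <- sample(npw)
      tree <- if (npw >= 2L)
        cbind(ord[-1L], vapply(2:npw, function(j) ord[sample.int(j - 1L, 1L)],
                               integer(1L)))
      else NULL
      for (r in seq_len(config$cross_pathway_reactions)) {
        ij <- if (!is.null(tree) && r <= nrow(tree)) tree[r, ] else sample(npw, 2L)
        subs <- sample(compounds[[ij[1L]]], 1L, prob = zipf_w(cpp))
        prods <- sample(compounds[[ij[2L]]], 1L, prob = zipf_w(cpp))
        lines <- c(lines, emit(pw_ids[ij[1L]], subs, prods, draw_direction()))
      }
    }
    iso_compounds <- character()
    if (config$isolated_component_count > 0L) {
      for (r in seq_len(config$isolated_component_count)) {
        pair <- sprintf("C9%04d", 2L * r - c(1L, 0L))
        iso_compounds <- c(iso_compounds, pair)
        lines <- c(lines, emit("00000", pair[1L], pair[2L], "forward"))
      }
    }
    if (!length(lines)) stop("configuration produced zero reactions")

    compound_pathways <- data.frame(
      compound = unlist(compounds),
      pathway = rep(pw_ids, each = cpp),
      stringsAsFactors = FALSE)
    pathway_category <- data.frame(pathway = pw_ids, category = cats,
                                   stringsAsFactors = FALSE)

    records <- parse_reaction_list(lines, currency = currency)
    net <- build_network(records, compound_pathways, pathway_category)

    module_of <- stats::setNames(rep(seq_len(npw), each = cpp), unlist(compounds))
    iso_idx <- npw + seq_len(config$isolated_component_count)
    if (length(iso_compounds))
      module_of <- c(module_of,
                     stats::setNames(rep(iso_idx, each = 2L), iso_compounds))

    diff_set <- plant_differential(net, pathway = pw_ids[1L],
                                   n_in_pathway = 8L, n_background = 12L,
                                   hub_bias = hub_bias,
                                   seed = config$seed + 1000L)
    target <- plant_target(net, diff_set, size = 15L,
                           seed = config$seed + 2000L)

    truth <- list(planted_modules = module_of,
                  planted_enriched_pathway = pw_ids[1L],
                  planted_differential = diff_set,
                  planted_target = target)

    out <- list(reactions = lines, compound_pathways = compound_pathways,
                pathway_category = pathway_category, currency = currency,
                network = net, truth = truth)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      writeLines(lines, file.path(dir, "reactions.lst"))
      utils::write.table(compound_pathways, file.path(dir, "compound_pathways.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(pathway_category, file.path(dir, "pathway_category.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_node_set(diff_set, file.path(dir, "differential.tsv"))
      write_node_set(target, file.path(dir, "target.tsv"))
      sidecar <- list(
        seed = config$seed,
        currency = currency,
        planted_modules = as.list(truth$planted_modules),
        planted_enriched_pathway = truth$planted_enriched_pathway,
        planted_differential = as.list(stats::setNames(
          diff_set$regulation, diff_set$compound)),
        planted_target = target$compound)
      jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    out
  })
}

#' Plant a differential metabolite set with known structure
#'
#' Samples `n_in_pathway` members from the compounds of a target pathway
#' present in the network and `n_background` from the remaining network
#' nodes. Sampling weight is proportional to `1 + hub_bias * total degree`,
#' so `hub_bias = 0` is uniform and large values concentrate the set on
#' hubs (emulating the observed centrality elevation of disease-associated
#' metabolite sets). Each member is assigned a +1/-1 regulation uniformly.
#'
#' @param net a [metabolic_network()].
#' @param pathway pathway id to enrich in.
#' @param n_in_pathway,n_background member counts.
#' @param hub_bias nonnegative weight on total degree.
#' @param seed integer seed.
#' @return a [node_set()] with regulation.
#' @export
plant_differential <- function(net, pathway, n_in_pathway, n_background,
                               hub_bias = 0, seed = 1L) {
  stopifnot(inherits(net, "metabolic_network"), hub_bias >= 0)
  nodes <- net_nodes(net)
  ann <- names(net$compound_pathways)[
    vapply(net$compound_pathways, function(p) pathway %in% p, logical(1L))]
  in_pool <- intersect(nodes, ann)
  bg_pool <- setdiff(nodes, in_pool)
  if (length(in_pool) < n_in_pathway || length(bg_pool) < n_background)
    stop("insufficient candidates for planting (pathway ", pathway, ")")
  deg <- igraph::degree(net$graph, mode = "all")
  with_seed(seed, {
    pick <- function(pool, k) {
      if (k == 0L) return(character())
      w <- 1 + hub_bias * deg[pool]
      sample(pool, k, prob = w)
    }
    members <- c(pick(in_pool, n_in_pathway), pick(bg_pool, n_background))
    node_set(members, regulation = sample(c(-1L, 1L), length(members),
                                          replace = TRUE))
  })
}

#' Plant a proximal target metabolite set
#'
#' Builds a set proximal to the differential set from within its directed
#' distance-2 ball, emulating a biologically proximal system (such as
#' neuro-endocrine metabolites around a differential signature). To spread
#' the proximity over the whole differential set rather than a single
#' neighbourhood, members are drawn by cycling over the differential
#' compounds in seeded random order, each contributing one of its direct
#' (either-direction) neighbours; when direct neighbours are exhausted the
#' remainder is drawn uniformly from the rest of the distance-2 ball.
#' Members of `diff` itself are excluded so proximity measures between-set
#' structure.
#'
#' @param net a [metabolic_network()].
#' @param diff a [node_set()] (or character vector).
#' @param size number of members to draw.
#' @param seed integer seed.
#' @return a [node_set()] (no regulation).
#' @export
plant_target <- function(net, diff, size, seed = 1L) {
  stopifnot(inherits(net, "metabolic_network"))
  members <- intersect(set_members(diff), net_nodes(net))
  if (!length(members)) stop("differential set disjoint from network")
  g <- net$graph
  ball_out <- igraph::ego(g, order = 2L, nodes = members, mode = "out")
  ball_in <- igraph::ego(g, order = 2L, nodes = members, mode = "in")
  pool <- setdiff(unique(unlist(lapply(c(ball_out, ball_in), names))), members)
  if (length(pool) < size)
    stop("insufficient candidates within distance 2 of the differential set")
  nbrs <- lapply(members, function(v)
    setdiff(names(igraph::neighbors(g, v, mode = "all")), members))
  with_seed(seed, {
    chosen <- character()
    ord <- rep(sample(seq_along(members)), length.out = 10L * size)
    for (i in ord) {
      if (length(chosen) >= size) break
      cand <- setdiff(nbrs[[i]], chosen)
      if (length(cand)) chosen <- c(chosen, sample(cand, 1L))
    }
    if (length(chosen) < size) {
      rest <- setdiff(pool, chosen)
      chosen <- c(chosen, sample(rest, size - length(chosen)))
    }
    node_set(chosen)
  })
}

# Evaluate `expr` under a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
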