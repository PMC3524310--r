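#' Parse a flat pipeline configuration file
#'
#' The configuration is line-oriented `key: value` text (`#` comments and
#' blank lines skipped). Unknown keys are rejected so typos fail loudly.
#' Recognised keys, all optional unless a stage needs them:
#'
#' * paths: `reactions`, `compound_pathways`, `pathway_category`,
#'   `differential`, `target`, `outdir`
#' * parameters: `currency` (comma-separated ids, or `default`),
#'   `replicates`, `k_clusters`, `radius`, `seed`, `sa_cooling`, `sa_f`,
#'   `sa_t0`, `partition_replicates`, `max_len`
#' * flags: `population_mode` (annotated/network), `formats`
#'   (comma-separated subset of graphml,sif,edgelist)
#'
#' @param path config file path, or a character vector of lines.
#' @param overrides named list applied on top of the file (same keys).
#' @return named list of class `run_config` with parsed values and
#'   defaults filled in.
#' @export
parse_run_config <- function(path, overrides = list()) {
  defaults <- list(reactions = NULL, compound_pathways = NULL,
                   pathway_category = NULL, differential = NULL,
                   target = NULL, outdir = ".",
                   currency = "default", replicates = 1000,
                   k_clusters = 3, radius = 2, seed = 1,
                   sa_cooling = 0.995, sa_f = 1, sa_t0 = NA,
                   partition_replicates = 50, max_len = 2,
                   population_mode = "annotated", formats = "graphml")
  vals <- list()
  if (!is.null(path)) {
    lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*\\S)\\s*$", ln))[[1L]]
      if (length(m) != 3L) stop("malformed config line: ", ln)
      vals[[m[2L]]] <- m[3L]
    }
  }
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(vals)] <- vals
  num_keys <- c("replicates", "k_clusters", "radius", "seed", "sa_cooling",
                "sa_f", "sa_t0", "partition_replicates", "max_len")
  for (k in num_keys) cfg[[k]] <- suppressWarnings(as.numeric(cfg[[k]]))
  cfg$seed <- as.integer(cfg$seed)
  cfg$currency_ids <- if (identical(cfg$currency, "default")) default_currency()
    else trimws(strsplit(cfg$currency, ",", fixed = TRUE)[[1L]])
  class(cfg) <- "run_config"
  cfg
}

cfg_path <- function(cfg, key, default_file) {
  p <- cfg[[key]]
  if (is.null(p)) p <- file.path(cfg$outdir, "input", default_file)
  p
}

require_file <- function(path, what) {
  if (!file.exists(path)) stop(what, " not found: ", path, call. = FALSE)
  path
}

write_manifest <- function(cfg, stage, inputs, outputs, params = list()) {
  hashes <- vapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_, "")
  manifest <- list(stage = stage, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("metabonet")),
                   inputs = as.list(hashes), outputs = outputs,
                   parameters = params)
  jsonlite::write_json(manifest,
                       file.path(cfg$outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

load_background <- function(cfg) {
  rx <- require_file(cfg_path(cfg, "reactions", "reactions.lst"), "reaction list")
  cp <- require_file(cfg_path(cfg, "compound_pathways", "compound_pathways.tsv"),
                     "compound-pathway annotation")
  pc <- require_file(cfg_path(cfg, "pathway_category", "pathway_category.tsv"),
                     "pathway-category annotation")
  records <- parse_reaction_list(rx, currency = cfg$currency_ids)
  build_network(records, read_annotations(cp), read_categories(pc))
}

load_differential <- function(cfg) {
  read_node_set(require_file(cfg_path(cfg, "differential", "differential.tsv"),
                             "differential metabolite set"))
}

#' Run one pipeline stage
#'
#' Stages mirror the analysis: `simulate` writes synthetic inputs under
#' `<outdir>/input`; `build` constructs the background network and its
#' bow-tie decomposition; `topo` the centrality table and differential-set
#' summary; `nulls` the random-set Z-score report; `decompose` the SA
#' partition, expansion, module compositions and Ward clusters; `enrich`
#' the cluster and pathway enrichment tables; `proximity` the proximity
#' report and simplified subnetwork; `core` the annotated core network.
#' Every stage writes a JSON manifest recording input hashes, parameters
#' and the seed. Reruns with identical config and seed produce
#' byte-identical tables.
#'
#' @param stage stage name, see above.
#' @param config a [parse_run_config()] result (or a path handed to it).
#' @param overrides named list of config overrides.
#' @return invisible character vector of written files.
#' @export
run_stage <- function(stage = c("simulate", "build", "topo", "nulls",
                                "decompose", "enrich", "proximity", "core"),
                      config, overrides = list()) {
  stage <- match.arg(stage)
  cfg <- if (inherits(config, "run_config")) {
    if (length(overrides)) stop("pass overrides together with a config path")
    config
  } else parse_run_config(config, overrides)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(stage,
    simulate = stage_simulate(cfg), build = stage_build(cfg),
    topo = stage_topo(cfg), nulls = stage_nulls(cfg),
    decompose = stage_decompose(cfg), enrich = stage_enrich(cfg),
    proximity = stage_proximity(cfg), core = stage_core(cfg))
  invisible(out)
}

stage_simulate <- function(cfg) {
  dir <- file.path(cfg$outdir, "input")
  sim <- generate_synthetic(synth_config(seed = cfg$seed), dir = dir)
  files <- file.path(dir, c("reactions.lst", "compound_pathways.tsv",
                            "pathway_category.tsv", "differential.tsv",
                            "target.tsv", "ground_truth.json"))
  write_manifest(cfg, "simulate", character(), files,
                 list(generator = unclass(synth_config(seed = cfg$seed))))
  files
}

stage_build <- function(cfg) {
  net <- load_background(cfg)
  files <- character()
  for (fmt in trimws(strsplit(cfg$formats, ",")[[1L]])) {
    f <- file.path(cfg$outdir, paste0("network.", fmt,
                                      if (fmt == "edgelist") ".tsv" else ""))
    write_network(net, f, format = fmt)
    files <- c(files, f)
  }
  bt <- bow_tie(net)
  btf <- file.path(cfg$outdir, "bowtie.tsv")
  btd <- data.frame(node = unlist(bt, use.names = FALSE),
                    component = rep(names(bt), lengths(bt)))
  btd <- btd[order(btd$node), ]
  utils::write.table(btd, btf, sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- file.path(cfg$outdir, "network_summary.json")
  jsonlite::write_json(list(nodes = n_nodes(net), arcs = n_arcs(net),
                            mean_degree = n_arcs(net) / n_nodes(net),
                            gsc = length(bt$gsc),
                            isolated = length(bt$isolated)),
                       sm, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, btf, sm)
  write_manifest(cfg, "build",
                 c(cfg_path(cfg, "reactions", "reactions.lst"),
                   cfg_path(cfg, "compound_pathways", "compound_pathways.tsv"),
                   cfg_path(cfg, "pathway_category", "pathway_category.tsv")),
                 files, list(currency = cfg$currency_ids))
  files
}

stage_topo <- function(cfg) {
  net <- load_background(cfg)
  diff <- load_differential(cfg)
  tab <- centrality_table(net)
  f1 <- file.path(cfg$outdir, "centralities.tsv")
  write_centralities(tab, f1)
  sm <- set_summary(tab, diff)
  f2 <- file.path(cfg$outdir, "set_summary.json")
  jsonlite::write_json(c(list(n_found = sm$n_found, n_set = sm$n_set),
                         as.list(sm$means)),
                       f2, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(cfg, "topo",
                 cfg_path(cfg, "differential", "differential.tsv"),
                 c(f1, f2))
  c(f1, f2)
}

stage_nulls <- function(cfg) {
  net <- load_background(cfg)
  diff <- load_differential(cfg)
  zs <- centrality_zscores(net, diff, replicates = cfg$replicates,
                           seed = cfg$seed)
  f1 <- file.path(cfg$outdir, "centrality_zscores.tsv")
  utils::write.table(zs, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "nulls",
                 cfg_path(cfg, "differential", "differential.tsv"), f1,
                 list(replicates = cfg$replicates))
  f1
}

stage_decompose <- function(cfg) {
  net <- load_background(cfg)
  core_part <- remove_isolated(net)
  part <- sa_partition(core_part,
                       T0 = if (is.na(cfg$sa_t0)) NULL else cfg$sa_t0,
                       cooling = cfg$sa_cooling, f = cfg$sa_f,
                       seed = cfg$seed)
  expanded <- expand_partition(net, part)
  comp <- module_composition(net, expanded)
  k <- min(cfg$k_clusters, nrow(comp))
  cut <- ward_cluster(comp, k)
  zq <- partition_null_z(net, expanded, R = cfg$partition_replicates,
                         seed = cfg$seed)
  f1 <- file.path(cfg$outdir, "partition.tsv")
  pd <- data.frame(node = names(expanded$assignment),
                   module = unname(expanded$assignment))
  pd <- pd[order(pd$node), ]
  utils::write.table(pd, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(cfg$outdir, "composition.tsv")
  utils::write.table(data.frame(module = rownames(comp), unclass(comp),
                                check.names = FALSE),
                     f2, sep = "\t", quote = FALSE, row.names = FALSE)
  f3 <- file.path(cfg$outdir, "clusters.tsv")
  utils::write.table(data.frame(module = names(cut$assignment),
                                cluster = unname(cut$assignment)),
                     f3, sep = "\t", quote = FALSE, row.names = FALSE)
  f4 <- file.path(cfg$outdir, "decomposition.json")
  jsonlite::write_json(list(modularity = expanded$modularity,
                            n_modules = expanded$n_modules,
                            core_modularity = part$modularity,
                            z_modularity = zq$z, k_clusters = k),
                       f4, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(cfg, "decompose",
                 cfg_path(cfg, "reactions", "reactions.lst"),
                 c(f1, f2, f3, f4),
                 list(sa_cooling = cfg$sa_cooling, sa_f = cfg$sa_f,
                      k_clusters = k,
                      partition_replicates = cfg$partition_replicates))
  c(f1, f2, f3, f4)
}

stage_enrich <- function(cfg) {
  net <- load_background(cfg)
  diff <- load_differential(cfg)
  pf <- file.path(cfg$outdir, "partition.tsv")
  cf <- file.path(cfg$outdir, "clusters.tsv")
  if (!file.exists(pf) || !file.exists(cf))
    stop("partition not found: run the decompose stage first (expected ",
         pf, ")", call. = FALSE)
  pd <- utils::read.table(pf, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  cd <- utils::read.table(cf, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  assignment <- stats::setNames(pd$module, pd$node)
  cut <- structure(list(tree = NULL, k = max(cd$cluster),
                        assignment = stats::setNames(cd$cluster, cd$module)),
                   class = "cluster_cut")
  ce <- cluster_enrichment(cut, assignment, diff)
  pe <- pathway_enrichment(net, diff, population = cfg$population_mode)
  f1 <- file.path(cfg$outdir, "cluster_enrichment.tsv")
  f2 <- file.path(cfg$outdir, "pathway_enrichment.tsv")
  write_enrichment(ce, f1)
  write_enrichment(pe, f2)
  write_manifest(cfg, "enrich", c(pf, cf), c(f1, f2),
                 list(population_mode = cfg$population_mode))
  c(f1, f2)
}

stage_proximity <- function(cfg) {
  net <- load_background(cfg)
  diff <- load_differential(cfg)
  target <- read_node_set(require_file(cfg_path(cfg, "target", "target.tsv"),
                                       "target metabolite set"))
  px <- proximity(net, diff, target, R = cfg$replicates, seed = cfg$seed)
  f1 <- file.path(cfg$outdir, "proximity.json")
  jsonlite::write_json(list(connectivity = px$connectivity,
                            connectivity_rate = px$connectivity_rate,
                            distance = px$distance, coverage = px$coverage,
                            z_connectivity = px$z_connectivity,
                            z_distance = px$z_distance,
                            replicates = cfg$replicates, seed = cfg$seed),
                       f1, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  f2 <- file.path(cfg$outdir, "proximity_null.tsv")
  utils::write.table(data.frame(connectivity = px$null_connectivity$values,
                                distance = px$null_distance$values),
                     f2, sep = "\t", quote = FALSE, row.names = FALSE)
  sub <- simplified_subnet(net, diff, target, max_len = cfg$max_len)
  f3 <- file.path(cfg$outdir, "subnet.graphml")
  igraph::write_graph(sub$graph, f3, format = "graphml")
  write_manifest(cfg, "proximity",
                 cfg_path(cfg, "target", "target.tsv"), c(f1, f2, f3),
                 list(replicates = cfg$replicates, max_len = cfg$max_len))
  c(f1, f2, f3)
}

stage_core <- function(cfg) {
  net <- load_background(cfg)
  diff <- load_differential(cfg)
  ef <- file.path(cfg$outdir, "pathway_enrichment.tsv")
  if (!file.exists(ef))
    stop("pathway enrichment not found: run the enrich stage first (expected ",
         ef, ")", call. = FALSE)
  pe <- utils::read.table(ef, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character")
  enriched <- pe$label[pe$enriched == "TRUE"]
  if (!length(enriched)) enriched <- pe$label[which.min(as.numeric(pe$p))]
  core <- build_core(net, enriched, diff, radius = cfg$radius)
  f1 <- file.path(cfg$outdir, "core.graphml")
  write_core(core, f1, format = "graphml")
  f2 <- file.path(cfg$outdir, "core_attributes.tsv")
  utils::write.table(core$attributes, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(cfg, "core", ef, c(f1, f2), list(radius = cfg$radius))
  c(f1, f2)
}
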