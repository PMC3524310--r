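#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` category members when drawing
#' `n` items without replacement from a population of `N` containing `K`
#' category members:
#' `p = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' Evaluated through the log-space hypergeometric CDF for numerical
#' stability. Vectorised over its arguments.
#'
#' @param N population size.
#' @param K category size (`K <= N`).
#' @param n number of draws (`n <= N`).
#' @param k observed hits (`k <= min(K, n)`).
#' @return upper-tail probability in `[0, 1]` (`k = 0` gives 1).
#' @export
hyper_tail <- function(N, K, n, k) {
  args <- cbind(N, K, n, k)
  N <- args[, 1L]; K <- args[, 2L]; n <- args[, 3L]; k <- args[, 4L]
  if (any(c(N, K, n, k) < 0)) stop("all arguments must be nonnegative")
  if (any(K > N)) stop("K must not exceed N")
  if (any(n > N)) stop("n must not exceed N")
  if (any(k > pmin(K, n))) stop("k must not exceed min(K, n)")
  unname(exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                           log.p = TRUE)))
}

new_enrichment <- function(df, N, n) {
  df <- df[order(df$p, df$label), , drop = FALSE]
  rownames(df) <- NULL
  df$enriched <- df$p < 0.05
  df$p_adj <- stats::p.adjust(df$p, method = "BH")  # supplementary only
  attr(df, "N") <- N
  attr(df, "n") <- n
  class(df) <- c("enrichment", "data.frame")
  df
}

#' Differential-set enrichment in module clusters
#'
#' One hypergeometric upper-tail test per cluster. The population is the
#' set of nodes assigned to modules (`N`), the draws are the differential
#' members among them (`n`); for each cluster, `K` counts the nodes of
#' its modules and `k` the differential members among those. A cluster
#' with `p < 0.05` is flagged enriched (raw p; a Benjamini-Hochberg
#' column is included for reference but never gates the flag).
#'
#' @param clusters a [ward_cluster()] cut.
#' @param partition a [partition][sa_partition()] or named assignment over
#'   the same modules.
#' @param diff a [node_set()] or character vector of differential
#'   compounds.
#' @return data.frame of class `enrichment`, rows sorted by `p`
#'   ascending, with columns `label`, `modules`, `K`, `k`, `p`,
#'   `enriched`, `p_adj`; `N` and `n` as attributes.
#' @export
cluster_enrichment <- function(clusters, partition, diff) {
  stopifnot(inherits(clusters, "cluster_cut"))
  assignment <- as_assignment(partition)
  mod_of_cluster <- split(names(clusters$assignment), clusters$assignment)
  if (!all(as.character(assignment) %in% names(clusters$assignment)))
    stop("partition contains modules absent from the cluster cut")
  members <- set_members(diff)
  N <- length(assignment)
  hits <- names(assignment) %in% members
  n <- sum(hits)
  rows <- lapply(names(mod_of_cluster), function(cl) {
    in_cl <- as.character(assignment) %in% mod_of_cluster[[cl]]
    K <- sum(in_cl)
    k <- sum(in_cl & hits)
    data.frame(label = paste("cluster", cl),
               modules = paste(mod_of_cluster[[cl]], collapse = ","),
               K = K, k = k, p = hyper_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  new_enrichment(do.call(rbind, rows), N, n)
}

#' Differential-set enrichment in pathways
#'
#' One hypergeometric upper-tail test per annotated pathway. The
#' population depends on `population`: `"annotated"` (default) takes all
#' network compounds carrying at least one pathway annotation,
#' `"network"` all network compounds, `"custom"` a user-supplied `N`
#' (with `n` the differential members in the network unless also given).
#' Per pathway, `K` counts its annotated compounds within the population
#' and `k` the differential members among them.
#'
#' @param net a [metabolic_network()] with pathway annotations.
#' @param diff a [node_set()] or character vector.
#' @param population population mode, see above.
#' @param N,n population and draw counts for `population = "custom"`.
#' @return data.frame of class `enrichment` (see
#'   [cluster_enrichment()]), one row per pathway.
#' @export
pathway_enrichment <- function(net, diff,
                               population = c("annotated", "network", "custom"),
                               N = NULL, n = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  population <- match.arg(population)
  cp <- net$compound_pathways
  nodes <- net_nodes(net)
  annotated <- intersect(names(cp), nodes)
  if (!length(annotated)) stop("network has no pathway annotations")
  members <- intersect(set_members(diff), nodes)
  pop <- switch(population, annotated = annotated, network = nodes,
                custom = annotated)
  Npop <- switch(population,
                 annotated = length(annotated),
                 network = length(nodes),
                 custom = { if (is.null(N)) stop("custom population needs N"); N })
  npop <- if (population == "custom" && !is.null(n)) n
          else length(intersect(members, pop))
  pw_members <- split(rep(names(cp), lengths(cp)), unlist(cp))
  rows <- lapply(names(pw_members), function(pw) {
    in_pw <- intersect(pw_members[[pw]], pop)
    K <- length(in_pw)
    k <- length(intersect(in_pw, members))
    if (K == 0L) return(NULL)
    data.frame(label = pw, modules = NA_character_, K = K, k = k,
               p = hyper_tail(Npop, K, npop, k), stringsAsFactors = FALSE)
  })
  new_enrichment(do.call(rbind, rows), Npop, npop)
}

#' @export
print.enrichment <- function(x, ...) {
  cat(sprintf("Hypergeometric enrichment (N = %d, n = %d):\n",
              attr(x, "N"), attr(x, "n")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write an enrichment table as TSV
#'
#' Columns label, modules, K, k, p, enriched, p_adj; the population sizes
#' N and n are recorded in a `#` header comment.
#'
#' @param x an `enrichment` data.frame.
#' @param path file path.
#' @export
write_enrichment <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N=%d n=%d", attr(x, "N"), attr(x, "n")), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
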