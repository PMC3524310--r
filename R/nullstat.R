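#' Null distribution of a set-level statistic over random node sets
#'
#' Monte-Carlo reference distribution for any statistic of a metabolite
#' set: each replicate draws `set_size` distinct nodes uniformly without
#' replacement from all network nodes and evaluates `statistic` on them.
#' This mirrors the unconstrained random-set control (no degree matching).
#'
#' @param net a [metabolic_network()].
#' @param set_size nodes per random set; must not exceed the network size.
#' @param statistic `function(net, nodes) -> number`; see
#'   [stat_mean_degree()] for ready-made, precomputed variants.
#' @param replicates number of random sets (default `1e5`, the scale used
#'   for genome-scale networks; desk-scale analyses typically pass `1e3`).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param statistic_name label stored in the result.
#' @return object of class `null_distribution`: list with
#'   `statistic_name`, `replicates`, `values`, `mean`, `sd` (sample
#'   standard deviation), `seed`.
#' @export
null_distribution <- function(net, set_size, statistic, replicates = 1e5,
                              seed = 1L, statistic_name = "statistic") {
  stopifnot(inherits(net, "metabolic_network"), is.function(statistic))
  n <- n_nodes(net)
  if (set_size > n) stop("set_size exceeds network size")
  replicates <- as.integer(replicates)
  if (replicates < 2L) stop("need at least 2 replicates")
  nodes <- net_nodes(net)
  values <- with_seed(seed, vapply(seq_len(replicates), function(i)
    as.numeric(statistic(net, nodes[sample.int(n, set_size)])),
    numeric(1L)))
  bad <- !is.finite(values)
  if (any(bad)) {
    warning(sum(bad), " replicate(s) yielded a non-finite statistic; dropped")
    values <- values[!bad]
    if (length(values) < 2L) stop("too few finite replicates")
  }
  structure(list(statistic_name = statistic_name,
                 replicates = length(values), values = values,
                 mean = mean(values), sd = stats::sd(values), seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Null distribution of %s: %d replicates, mean %.4g, sd %.4g (seed %d)\n",
              x$statistic_name, x$replicates, x$mean, x$sd, x$seed))
  invisible(x)
}

#' @export
plot.null_distribution <- function(x, observed = NULL, ...) {
  graphics::hist(x$values, breaks = 40, col = "grey85", border = "white",
                 main = paste("Null:", x$statistic_name),
                 xlab = x$statistic_name, ...)
  if (!is.null(observed)) graphics::abline(v = observed, col = "red3", lwd = 2)
  invisible(x)
}

#' Z-score of an observed set statistic against its null
#'
#' `Z = (observed - null mean) / null sd`; the conventional threshold
#' `|Z| > 2.33` (one-sided 0.01 normal quantile) flags significance.
#'
#' @param observed observed statistic value.
#' @param null a [null_distribution()] with positive sd.
#' @param threshold significance threshold on `|Z|`.
#' @return object of class `z_score`: list with `observed`, `null_mean`,
#'   `null_sd`, `z`, `significant`, `threshold`.
#' @export
z_score <- function(observed, null, threshold = 2.33) {
  if (!is.list(null) || is.null(null$sd)) stop("'null' must be a null_distribution")
  if (!is.finite(null$sd) || null$sd <= 0) stop("degenerate null")
  z <- (observed - null$mean) / null$sd
  structure(list(observed = observed, null_mean = null$mean,
                 null_sd = null$sd, z = z,
                 significant = abs(z) > threshold, threshold = threshold),
            class = "z_score")
}

#' @export
print.z_score <- function(x, ...) {
  cat(sprintf("observed %.4g vs null %.4g +- %.4g: Z = %.3f (%ssignificant at |Z| > %.2f)\n",
              x$observed, x$null_mean, x$null_sd, x$z,
              if (x$significant) "" else "not ", x$threshold))
  invisible(x)
}

#' Precomputed set-statistic factories
#'
#' Return `function(net, nodes)` closures with the per-node quantity
#' precomputed on `net`, cheap enough for 1e5-replicate nulls. Available:
#' mean degree (`mode` "all"/"in"/"out"), mean closeness (either
#' direction) and mean betweenness over the set.
#'
#' @param net a [metabolic_network()].
#' @param mode degree mode for [stat_mean_degree()].
#' @param direction closeness direction for [stat_mean_closeness()].
#' @return a statistic function for [null_distribution()].
#' @export
stat_mean_degree <- function(net, mode = c("all", "in", "out")) {
  mode <- match.arg(mode)
  deg <- igraph::degree(net$graph, mode = mode)
  function(net, nodes) mean(deg[nodes])
}

#' @rdname stat_mean_degree
#' @export
stat_mean_closeness <- function(net, direction = c("out", "in")) {
  direction <- match.arg(direction)
  cl <- node_closeness(net, direction)
  function(net, nodes) mean(cl[nodes])
}

#' @rdname stat_mean_degree
#' @export
stat_mean_betweenness <- function(net) {
  b <- node_betweenness(net)
  function(net, nodes) mean(b[nodes])
}

#' Z-score report for a metabolite set's centralities
#'
#' Convenience wrapper reproducing the centrality-versus-random-sets
#' comparison for one set: observed set means of in-/out-degree, in-/out-
#' closeness and betweenness, each against an equal-size random-set null.
#'
#' @param net a [metabolic_network()].
#' @param set a [node_set()] or character vector (members outside the
#'   network are dropped; the random sets are drawn from all nodes).
#' @param replicates,seed passed to [null_distribution()].
#' @return data.frame with one row per centrality: observed, null mean,
#'   null sd, z, significant.
#' @export
centrality_zscores <- function(net, set, replicates = 1e3, seed = 1L) {
  members <- intersect(set_members(set), net_nodes(net))
  if (!length(members)) stop("set disjoint from network")
  stats_list <- list(
    in_degree = stat_mean_degree(net, "in"),
    out_degree = stat_mean_degree(net, "out"),
    closeness_in = stat_mean_closeness(net, "in"),
    closeness_out = stat_mean_closeness(net, "out"),
    betweenness = stat_mean_betweenness(net))
  rows <- lapply(seq_along(stats_list), function(i) {
    f <- stats_list[[i]]
    obs <- f(net, members)
    nd <- null_distribution(net, length(members), f, replicates,
                            seed = seed + i - 1L,
                            statistic_name = names(stats_list)[i])
    zs <- z_score(obs, nd)
    data.frame(statistic = names(stats_list)[i], observed = obs,
               null_mean = nd$mean, null_sd = nd$sd, z = zs$z,
               significant = zs$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  out
}
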