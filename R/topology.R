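#' Empirical degree distribution
#'
#' P(k) is the fraction of nodes with exactly k neighbours. All nodes,
#' including isolated ones, count towards the denominator, so the
#' probabilities always sum to one; degree zero is excluded later by the
#' power-law fit.
#'
#' @param net a non-empty `interaction_network`.
#' @return An object of class `degree_distribution`: data frame with
#'   columns `k` (observed degrees, ascending) and `p`.
#' @export
degree_distribution <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (n_nodes(net) == 0L) stop("degree distribution of an empty network is undefined")
  deg <- igraph::degree(as_igraph(net))
  tab <- table(deg)
  out <- data.frame(k = as.integer(names(tab)),
                    p = as.numeric(tab) / length(deg))
  out <- out[order(out$k), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("degree_distribution", "data.frame")
  out
}

#' Power-law fit of a degree distribution by log-log regression
#'
#' Fits the scale-free model P(k) ~ k^-gamma by ordinary least squares of
#' log10 P(k) on log10 k over the raw (unbinned) support with k >= 1, the
#' convention of Cytoscape's NetworkAnalyzer. Because the regression is run
#' on the raw observed distribution rather than a maximum-likelihood tail
#' fit, the estimated exponent can legitimately fall below 1.
#'
#' @param dist a `degree_distribution` (or data frame with columns `k`, `p`).
#' @return An object of class `power_law_fit`: list with `gamma` (degree
#'   exponent, the negated slope), `log_prefactor` (intercept of the
#'   regression, base-10 logs) and `r_squared`.
#' @export
fit_power_law <- function(dist) {
  stopifnot(is.data.frame(dist), all(c("k", "p") %in% names(dist)))
  d <- dist[dist$k >= 1 & dist$p > 0, , drop = FALSE]
  if (length(unique(d$k)) < 2L) {
    stop("power-law fit undefined: need at least 2 distinct degrees >= 1")
  }
  fit <- stats::lm(log10(p) ~ log10(k), data = d)
  # R^2 computed directly so an exact fit (zero residual, possibly constant
  # log P) reports 1 rather than NaN
  y <- log10(d$p)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(list(gamma = -unname(stats::coef(fit)[2]),
                 log_prefactor = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: gamma = %.3f, R^2 = %.3f\n",
              x$gamma, x$r_squared))
  invisible(x)
}

#' Average (local) clustering coefficient
#'
#' Mean over all nodes of 2 t(v) / (deg(v) (deg(v) - 1)), where t(v) is the
#' number of triangles through v; nodes of degree below 2 contribute zero.
#' The value excluding those nodes is reported by [topology_summary()] as
#' well, since network tools differ on this convention.
#'
#' @param net a non-empty `interaction_network`.
#' @return The average clustering coefficient in \[0, 1\].
#' @export
average_clustering <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (n_nodes(net) == 0L) stop("clustering coefficient of an empty network is undefined")
  igraph::transitivity(as_igraph(net), type = "localaverage", isolates = "zero")
}

#' Characteristic path length and diameter
#'
#' Both metrics are computed on the largest connected component, the single
#' finite-value convention of NetworkAnalyzer: the characteristic path
#' length is the mean shortest-path distance over connected node pairs and
#' the diameter is the maximum such distance.
#'
#' @param net a non-empty `interaction_network`.
#' @return List with `char_path_length` and `diameter`. A single-node
#'   component yields `(0, 0)` with a warning.
#' @export
path_metrics <- function(net) {
  comp <- largest_component(net)
  if (n_nodes(comp) < 2L) {
    warning("largest component has a single node; path metrics are 0")
    return(list(char_path_length = 0, diameter = 0L))
  }
  g <- as_igraph(comp)
  list(char_path_length = igraph::mean_distance(g, directed = FALSE),
       diameter = as.integer(igraph::diameter(g, directed = FALSE,
                                              unconnected = FALSE)))
}

#' Per-node degree and betweenness centrality
#'
#' Betweenness is the unnormalized shortest-path centrality of Brandes:
#' for node v the sum over unordered pairs s != t != v of the fraction of
#' shortest s-t paths passing through v. Rankings are invariant to the
#' normalization, so none is applied by default.
#'
#' With `use_confidence_weights = TRUE`, degree becomes the sum of incident
#' confidences (strength) and betweenness treats each edge as a distance of
#' 1/confidence, so high-confidence interactions are preferred routes.
#'
#' @param net a non-empty `interaction_network`.
#' @param use_confidence_weights use confidence-weighted variants.
#' @param normalized divide betweenness by 2/((n-1)(n-2)) pair counts.
#' @return Data frame `node`, `degree`, `betweenness`, in lexicographic
#'   node order.
#' @export
centrality_table <- function(net, use_confidence_weights = FALSE,
                             normalized = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  if (n_nodes(net) == 0L) stop("centrality of an empty network is undefined")
  g <- as_igraph(net)
  if (use_confidence_weights) {
    deg <- igraph::strength(g, weights = igraph::E(g)$confidence)
    btw <- igraph::betweenness(g, directed = FALSE, normalized = normalized,
                               weights = 1 / igraph::E(g)$confidence)
  } else {
    deg <- igraph::degree(g)
    btw <- igraph::betweenness(g, directed = FALSE, normalized = normalized,
                               weights = NA)
  }
  data.frame(node = net$nodes, degree = unname(deg[net$nodes]),
             betweenness = unname(btw[net$nodes]),
             stringsAsFactors = FALSE)
}

#' Topological summary of an interaction network
#'
#' Bundles node/edge counts, the power-law fit of the degree distribution,
#' the average clustering coefficient (both the all-nodes convention and
#' the degree >= 2 variant), and the largest-component path metrics.
#'
#' @param net a non-empty `interaction_network`.
#' @return An object of class `topology_summary`.
#' @export
topology_summary <- function(net) {
  dist <- degree_distribution(net)
  fit <- tryCatch(fit_power_law(dist), error = function(e) NULL)
  pm <- path_metrics(net)
  g <- as_igraph(net)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  structure(list(
    n_nodes = n_nodes(net),
    n_edges = n_edges(net),
    fit = fit,
    avg_clustering = average_clustering(net),
    avg_clustering_min_deg2 = mean(local_cc, na.rm = TRUE),
    char_path_length = pm$char_path_length,
    diameter = pm$diameter
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("nodes: %d  edges: %d\n", x$n_nodes, x$n_edges))
  if (!is.null(x$fit)) {
    cat(sprintf("degree exponent gamma: %.3f (R^2 = %.3f)\n",
                x$fit$gamma, x$fit$r_squared))
  }
  cat(sprintf("avg clustering coefficient: %.3f (%.3f over deg >= 2 nodes)\n",
              x$avg_clustering, x$avg_clustering_min_deg2))
  cat(sprintf("characteristic path length: %.3f  diameter: %d\n",
              x$char_path_length, x$diameter))
  invisible(x)
}
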