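#' Rule-of-thumb cluster count
#'
#' The classical heuristic k = sqrt(n / 2) for choosing the number of
#' k-means clusters from the number of observations, rounded to the nearest
#' integer with a minimum of one. For a 201-node network it prescribes 10
#' clusters.
#'
#' @param n number of nodes (positive integer).
#' @return Integer cluster count.
#' @export
cluster_count_rule <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a positive integer")
  max(1L, as.integer(round(sqrt(n / 2))))
}

#' Partition a network by k-means on adjacency rows
#'
#' Each node is represented by its row of the network adjacency matrix
#' (binary by default, confidence-weighted behind a flag) and the rows are
#' clustered by [stats::kmeans()] in Euclidean space with `n_init` random
#' restarts keeping the lowest within-cluster sum of squares. The result is
#' reproducible for a given `seed`; the caller's RNG state is untouched.
#'
#' @param net a non-empty `interaction_network`.
#' @param k number of clusters; defaults to [cluster_count_rule()] applied
#'   to the node count.
#' @param seed integer seed for centroid initialization.
#' @param use_confidence_weights cluster on confidence-weighted adjacency.
#' @param n_init random restarts (best inertia kept).
#' @param max_iter maximum iterations per restart.
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (named integer vector, node -> cluster in 1..k), `k`, `seed`, and
#'   `inertia` (total within-cluster sum of squares).
#' @export
kmeans_partition <- function(net, k = NULL, seed = 1L,
                             use_confidence_weights = FALSE,
                             n_init = 10L, max_iter = 300L) {
  stopifnot(inherits(net, "interaction_network"))
  n <- n_nodes(net)
  if (n == 0L) stop("cannot cluster an empty network")
  if (is.null(k)) k <- cluster_count_rule(n)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= number of nodes")
  A <- adjacency_rows(net, use_confidence_weights)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  if (k == n) {
    # every node its own cluster; stats::kmeans requires k < n
    labels <- seq_len(n)
    km <- list(cluster = labels, tot.withinss = 0)
  } else {
    km <- stats::kmeans(A, centers = k, nstart = n_init, iter.max = max_iter)
  }
  labels <- as.integer(km$cluster)
  names(labels) <- rownames(A)
  structure(list(labels = labels, k = as.integer(k),
                 seed = as.integer(seed), inertia = km$tot.withinss),
            class = "cluster_assignment")
}

#' Adjacency-row feature matrix
#'
#' @param net an `interaction_network`.
#' @param use_confidence_weights fill entries with confidences instead of 1.
#' @return Dense n x n numeric matrix, rows/columns in node order.
#' @export
adjacency_rows <- function(net, use_confidence_weights = FALSE) {
  g <- as_igraph(net)
  A <- igraph::as_adjacency_matrix(
    g, sparse = FALSE,
    attr = if (use_confidence_weights) "confidence" else NULL)
  A[net$nodes, net$nodes, drop = FALSE]
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("k-means partition: k = %d, inertia = %.4f (seed %d)\n",
              x$k, x$inertia, x$seed))
  print(table(cluster = x$labels))
  invisible(x)
}
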