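# Independent brute-force oracles used to cross-check the package's graph
# and statistics code. These deliberately avoid igraph and the package's own
# computation paths: graphs are handled as plain adjacency matrices built
# straight from the edge table.

adj_from_net <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    for (i in seq_len(nrow(net$edges))) {
      a <- net$edges$protein_a[i]; b <- net$edges$protein_b[i]
      A[a, b] <- 1L; A[b, a] <- 1L
    }
  }
  A
}

# all-pairs shortest-path distances by breadth-first search
oracle_bfs_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(u) which(A[u, ] == 1L))))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

oracle_path_metrics <- function(A) {
  D <- oracle_bfs_dist(A)
  vals <- D[upper.tri(D)]
  vals <- vals[is.finite(vals)]
  list(char_path_length = mean(vals), diameter = max(vals))
}

# betweenness by explicit enumeration of every shortest path
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_bfs_dist(A)
  btw <- numeric(n)
  enum_paths <- function(s, t) {
    if (s == t) return(list(s))
    preds <- which(A[, t] == 1L & D[s, ] == D[s, t] - 1)
    out <- list()
    for (p in preds) {
      for (pp in enum_paths(s, p)) out <- c(out, list(c(pp, t)))
    }
    out
  }
  if (n >= 2) {
    for (s in 1:(n - 1)) {
      for (t in (s + 1):n) {
        if (!is.finite(D[s, t])) next
        paths <- enum_paths(s, t)
        np <- length(paths)
        for (pth in paths) {
          interior <- setdiff(pth, c(s, t))
          btw[interior] <- btw[interior] + 1 / np
        }
      }
    }
  }
  stats::setNames(btw, rownames(A))
}

# average local clustering by exhaustive neighbour-pair triangle counting
oracle_avg_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1L)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) links <- links + A[nb[i], nb[j]]
    cc[v] <- 2 * links / (k * (k - 1))
  }
  mean(cc)
}

is_connected_oracle <- function(A) all(is.finite(oracle_bfs_dist(A)))

# Erdos-Renyi style random network on named nodes
random_network <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  nodes <- sprintf("N%02d", seq_len(n))
  edges <- data.frame(protein_a = nodes[pairs[keep, 1]],
                      protein_b = nodes[pairs[keep, 2]],
                      confidence = stats::runif(sum(keep), 0.4, 1))
  interaction_network(edges, nodes = nodes)
}

random_connected_network <- function(n, p = 0.4, seed = 1) {
  repeat {
    net <- random_network(n, p, seed)
    if (n_edges(net) > 0 && is_connected_oracle(adj_from_net(net))) return(net)
    seed <- seed + 10000
  }
}

# direct combinatorial hypergeometric upper tail
oracle_hyper_tail <- function(overlap, n_category, n_query, n_background) {
  ks <- overlap:min(n_category, n_query)
  sum(choose(n_category, ks) * choose(n_background - n_category, n_query - ks)) /
    choose(n_background, n_query)
}

# Benjamini-Hochberg step-up from its textbook definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  vals <- p[o] * m / seq_len(m)
  vals <- rev(cummin(rev(vals)))
  adj <- numeric(m)
  adj[o] <- pmin(vals, 1)
  adj
}

# exhaustive minimum within-cluster sum of squares over all 2-partitions
oracle_min_inertia_2part <- function(X) {
  n <- nrow(X)
  wss <- function(idx) {
    ctr <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, ctr)^2)
  }
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    lab <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1)])
    g2 <- which(lab == 1L)
    if (!length(g2)) next
    tot <- wss(which(lab == 0L)) + wss(g2)
    if (tot < best) best <- tot
  }
  best
}

# small fixed networks used across tests
triangle_net <- function() {
  interaction_network(data.frame(protein_a = c("A", "B", "A"),
                                 protein_b = c("B", "C", "C"),
                                 confidence = c(0.95, 0.91, 0.92)))
}

star_net <- function(leaves = 4) {
  interaction_network(data.frame(protein_a = "C0",
                                 protein_b = sprintf("L%d", seq_len(leaves)),
                                 confidence = 0.9))
}

path_net <- function(nodes = c("A", "B", "C")) {
  k <- length(nodes)
  interaction_network(data.frame(protein_a = nodes[-k], protein_b = nodes[-1],
                                 confidence = 0.9))
}

two_cliques_net <- function(size = 5) {
  clique_edges <- function(nodes) {
    pr <- t(utils::combn(nodes, 2))
    data.frame(protein_a = pr[, 1], protein_b = pr[, 2], confidence = 0.95)
  }
  interaction_network(rbind(clique_edges(sprintf("A%d", seq_len(size))),
                            clique_edges(sprintf("B%d", seq_len(size)))))
}
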