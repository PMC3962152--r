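test_that("degree distributions normalize and match known shapes", {
  tri <- degree_distribution(triangle_net())
  expect_equal(tri$k, 2L)
  expect_equal(tri$p, 1)
  star <- degree_distribution(star_net(4))
  expect_equal(star$p[star$k == 1], 0.8)
  expect_equal(star$p[star$k == 4], 0.2)
  for (seed in 1:10) {
    d <- degree_distribution(random_network(9, 0.4, seed))
    expect_equal(sum(d$p), 1, tolerance = 1e-12)
  }
})

test_that("power-law fit recovers exact exponents and matches a closed-form
           regression oracle", {
  # exact P(k) = k^-2, renormalized: slope forced to -2, perfect fit
  k <- 1:5
  p <- k^-2 / sum(k^-2)
  fit <- fit_power_law(data.frame(k = k, p = p))
  expect_equal(fit$gamma, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # two support points always fit exactly
  fit2 <- fit_power_law(data.frame(k = c(1, 2), p = c(0.5, 0.5)))
  expect_equal(fit2$gamma, 0, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)

  # arbitrary distribution: compare with the closed-form least-squares slope
  set.seed(42)
  for (i in 1:5) {
    kk <- sort(sample(1:40, 8))
    pp <- runif(8); pp <- pp / sum(pp)
    fit <- fit_power_law(data.frame(k = kk, p = pp))
    x <- log10(kk); y <- log10(pp)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    r2 <- stats::cor(x, y)^2
    expect_equal(fit$gamma, -slope, tolerance = 1e-9)
    expect_equal(fit$r_squared, r2, tolerance = 1e-9)
  }

  expect_error(fit_power_law(data.frame(k = 3, p = 1)), "undefined")
})

test_that("clustering coefficient equals exhaustive triangle enumeration", {
  expect_equal(average_clustering(triangle_net()), 1)
  expect_equal(average_clustering(star_net(5)), 0)
  for (seed in 1:20) {
    net <- random_network(6 + seed %% 4, 0.45, seed)
    expect_equal(average_clustering(net),
                 oracle_avg_clustering(adj_from_net(net)),
                 tolerance = 1e-12)
  }
})

test_that("path metrics equal all-pairs BFS on the largest component", {
  pm <- path_metrics(path_net(c("A", "B", "C")))
  expect_equal(pm$char_path_length, 4 / 3)
  expect_equal(pm$diameter, 2L)
  k4 <- interaction_network(
    data.frame(a = c("A", "A", "A", "B", "B", "C"),
               b = c("B", "C", "D", "C", "D", "D"), s = 0.9))
  expect_equal(path_metrics(k4), list(char_path_length = 1, diameter = 1L))
  for (seed in 1:20) {
    net <- random_connected_network(8, 0.35, seed)
    pm <- path_metrics(net)
    orc <- oracle_path_metrics(adj_from_net(net))
    expect_equal(pm$char_path_length, orc$char_path_length, tolerance = 1e-12)
    expect_equal(pm$diameter, as.integer(orc$diameter))
  }
  expect_warning(pm1 <- path_metrics(interaction_network(nodes = "A")),
                 "single node")
  expect_equal(pm1$char_path_length, 0)
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  ct <- centrality_table(path_net(c("A", "B", "C")))
  expect_equal(ct$betweenness[ct$node == "B"], 1)
  expect_equal(ct$betweenness[ct$node != "B"], c(0, 0))
  star <- centrality_table(star_net(4))
  expect_equal(star$betweenness[star$node == "C0"], choose(4, 2))
  for (seed in 1:25) {
    net <- random_connected_network(7, 0.4, seed)
    ct <- centrality_table(net)
    orc <- oracle_betweenness(adj_from_net(net))
    expect_equal(ct$betweenness, unname(orc[ct$node]), tolerance = 1e-9)
    expect_equal(sum(ct$degree), 2 * n_edges(net))
  }
})

test_that("betweenness is equivariant under node relabeling", {
  net <- random_connected_network(8, 0.4, 3)
  ct <- centrality_table(net)
  # order-preserving relabeling: prefix every symbol identically
  relabeled <- interaction_network(
    data.frame(a = paste0("X", net$edges$protein_a),
               b = paste0("X", net$edges$protein_b),
               s = net$edges$confidence))
  ct2 <- centrality_table(relabeled)
  expect_equal(ct2$betweenness, ct$betweenness)
  expect_equal(ct2$degree, ct$degree)
})

test_that("adding an edge never increases diameter or path length", {
  for (seed in 1:10) {
    net <- random_connected_network(8, 0.3, seed)
    pm0 <- path_metrics(net)
    A <- adj_from_net(net)
    missing <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (!nrow(missing)) next
    pick <- missing[1 + seed %% nrow(missing), ]
    aug <- interaction_network(rbind(
      net$edges,
      data.frame(protein_a = net$nodes[pick[1]],
                 protein_b = net$nodes[pick[2]], confidence = 0.9)))
    pm1 <- path_metrics(aug)
    expect_lte(pm1$diameter, pm0$diameter)
    expect_lte(pm1$char_path_length, pm0$char_path_length)
  }
})

test_that("topology summary bundles consistent invariants", {
  net <- make_network(120, 2, seed = 5)
  ts <- topology_summary(net)
  expect_equal(ts$n_nodes, 120)
  expect_gte(ts$diameter, ts$char_path_length)
  expect_lte(ts$diameter, ts$n_nodes - 1)
  expect_true(ts$avg_clustering >= 0 && ts$avg_clustering <= 1)
  expect_true(ts$fit$r_squared >= 0 && ts$fit$r_squared <= 1)
})
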