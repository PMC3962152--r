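make_ds <- function(mat, n_normal, n_disease, name = "toy") {
  groups <- stats::setNames(rep(c("normal", "disease"), c(n_normal, n_disease)),
                            colnames(mat))
  expression_dataset(mat, groups, name = name)
}

test_that("pooled t-statistics match the classical test and handle
           degenerate genes", {
  set.seed(21)
  mat <- matrix(rnorm(10 * 8), 10, 8,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:8)))
  mat["g01", ] <- 5                      # identical everywhere
  mat["g02", ] <- c(rep(0, 4), rep(1, 4)) # zero variance, unequal means
  ds <- make_ds(mat, 4, 4)
  st <- differential_stats(ds)
  expect_equal(st$t_statistic[st$gene == "g01"], 0)
  expect_equal(st$p_value[st$gene == "g01"], 1)
  expect_equal(st$fold_change[st$gene == "g01"], 0)
  expect_true(st$degenerate[st$gene == "g02"])
  expect_equal(st$p_value[st$gene == "g02"], .Machine$double.xmin)
  # independent route: stats::t.test per gene
  for (g in sprintf("g%02d", 3:10)) {
    tt <- stats::t.test(mat[g, 5:8], mat[g, 1:4], var.equal = TRUE)
    expect_equal(st$t_statistic[st$gene == g], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(st$p_value[st$gene == g], tt$p.value, tolerance = 1e-10)
    expect_equal(st$fold_change[st$gene == g],
                 unname(tt$estimate[1] - tt$estimate[2]), tolerance = 1e-10)
  }
  # Welch variant agrees with t.test(var.equal = FALSE)
  stw <- differential_stats(ds, var_equal = FALSE)
  ttw <- stats::t.test(mat["g05", 5:8], mat["g05", 1:4])
  expect_equal(stw$t_statistic[stw$gene == "g05"], unname(ttw$statistic),
               tolerance = 1e-10)
  expect_equal(stw$p_value[stw$gene == "g05"], ttw$p.value, tolerance = 1e-10)
})

test_that("rank percentiles are class-wise bijections, monotone in p", {
  pair <- make_expression_pair(200, 10, 10, planted_fraction = 0.2,
                               effect_size = 2, seed = 31)
  st <- rank_percentiles(differential_stats(pair$a))
  for (cls in c("under", "over")) {
    sub <- st[st$direction == cls, ]
    expect_setequal(sub$rank, seq_len(nrow(sub)))
    expect_equal(min(sub$rank_percentile),
                 ceiling(100 * 1 / nrow(sub)))
    expect_equal(max(sub$rank_percentile), 100)
    ord <- order(sub$rank)
    expect_true(all(diff(sub$p_value[ord]) >= 0))
    expect_true(all(diff(sub$rank_percentile[ord]) >= 0))
  }
})

test_that("planted genes separate from nulls in the percentile ranking", {
  pair <- make_expression_pair(500, 20, 20, planted_fraction = 0.1,
                               effect_size = 3, seed = 77)
  st <- rank_percentiles(differential_stats(pair$a))
  planted_pct <- st$rank_percentile[st$gene %in% pair$planted]
  expect_lt(stats::median(planted_pct), 15)
  # at effect 3 s.d. and n = 20/20 the planted block dominates the top ranks
  expect_gt(mean(planted_pct <= 25), 0.95)
})

test_that("meta-combination applies presence, concordance and threshold
           rules", {
  a <- data.frame(gene = c("g1", "g2", "g3"),
                  p_value = c(1e-5, 1e-4, 1e-3),
                  fold_change = c(-2, 1.5, -1.2),
                  direction = c("under", "over", "under"))
  b <- data.frame(gene = c("g1", "g2", "g4"),
                  p_value = c(1e-6, 1e-3, 1e-2),
                  fold_change = c(-1.4, -1.3, 2.0),
                  direction = c("under", "under", "over"))
  a <- rank_percentiles(a); b <- rank_percentiles(b)
  m <- meta_combine(a, b, threshold_pct = 80)
  expect_equal(m$direction[m$gene == "g1"], "under")
  expect_true(m$passes_filter[m$gene == "g1"])
  expect_equal(m$direction[m$gene == "g2"], "discordant")  # sign flip
  expect_equal(m$direction[m$gene == "g3"], "absent")      # only in a
  expect_equal(m$direction[m$gene == "g4"], "absent")      # only in b
  expect_false(any(m$passes_filter[m$gene != "g1"]))
  # symmetric in the dataset arguments up to column naming
  m2 <- meta_combine(b, a, threshold_pct = 80)
  expect_equal(m2$direction, m$direction)
  expect_equal(m2$cumulative_percentile, m$cumulative_percentile)
})

test_that("published T-ALL summary classifies 16 under and 11 over", {
  tbl <- tall_hub_expression()
  m <- meta_from_printed(tbl)
  expect_equal(sum(m$direction == "under"), 16)
  expect_equal(sum(m$direction == "over"), 11)
  # the recomputed direction agrees with the printed grouping on every row
  expect_equal(m$direction[match(tbl$gene, m$gene)], tbl$printed_class)
  # mean-percentile rule: one printed row (EGFR, (34+39)/2 = 36.5) sits just
  # outside the top-36% cumulative cutoff and is flagged rather than passed
  expect_false(m$passes_filter[m$gene == "EGFR"])
  expect_equal(m$cumulative_percentile[m$gene == "EGFR"], 36.5)
  expect_equal(sum(m$passes_filter), 26)
})

test_that("hub expression classification restricts and partitions records", {
  hubs <- notch1_hub_genes()
  expect_length(hubs, 42)
  m <- meta_from_printed(tall_hub_expression())
  rep <- classify_hub_expression(hubs, m)
  expect_equal(unname(rep$counts["under"] + rep$counts["over"]), 27)
  expect_length(rep$unmeasured, 15)
  # empty intersection
  rep0 <- classify_hub_expression(c("NOPE1", "NOPE2"), m)
  expect_equal(sum(rep0$counts[c("under", "over", "discordant", "absent")]), 0)
  # random subset restriction equals a plain set filter
  set.seed(3)
  sub <- sample(m$gene, 10)
  rep_sub <- classify_hub_expression(sub, m)
  got <- sort(c(rep_sub$under$gene, rep_sub$over$gene, rep_sub$discordant$gene,
                rep_sub$absent$gene))
  expect_equal(got, sort(intersect(sub, m$gene)))
})

test_that("null data give calibrated type-I error rates", {
  pair <- make_expression_pair(2000, 20, 20, planted_fraction = 0,
                               effect_size = 0, seed = 19)
  st <- differential_stats(pair$a)
  frac <- mean(st$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})
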