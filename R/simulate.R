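#' Simulate a scale-free interaction network
#'
#' Barabasi-Albert preferential attachment via [igraph::sample_pa()]: each
#' arriving node attaches `attach_m` edges preferentially to high-degree
#' nodes, giving the connected, heavy-tailed degree structure of curated
#' protein-interaction networks. Edge confidences are drawn uniformly on
#' \[0.4, 1\] by default — the range of STRING combined scores above the
#' low-confidence floor — or fixed to a constant.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param attach_m edges added per arriving node (>= 1, < `n_nodes`).
#' @param confidence `"uniform"` or `"fixed"`.
#' @param conf_range lower/upper bounds of the uniform confidence law.
#' @param fixed_value confidence used when `confidence = "fixed"`.
#' @param seed integer seed; the result is reproducible and the caller's
#'   RNG state is untouched.
#' @return An `interaction_network` with nodes `G0001`, `G0002`, ...
#' @export
make_network <- function(n_nodes, attach_m = 3L,
                         confidence = c("uniform", "fixed"),
                         conf_range = c(0.4, 1), fixed_value = 0.95,
                         seed = 1L) {
  confidence <- match.arg(confidence)
  stopifnot(n_nodes >= 2, attach_m >= 1, attach_m < n_nodes)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, power = 1, m = attach_m, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  width <- max(4L, nchar(as.character(n_nodes)))
  sym <- sprintf(paste0("G%0", width, "d"), seq_len(n_nodes))
  conf <- switch(confidence,
    uniform = stats::runif(nrow(el), conf_range[1], conf_range[2]),
    fixed = rep(fixed_value, nrow(el)))
  interaction_network(data.frame(protein_a = sym[el[, 1]],
                                 protein_b = sym[el[, 2]],
                                 confidence = conf,
                                 stringsAsFactors = FALSE),
                      nodes = sym)
}

#' Simulate a pair of two-group expression datasets with planted signal
#'
#' Emulates two independent log-scale, median-centered microarray cohorts
#' measuring the same genes: Gaussian noise around zero, with a planted
#' subset of genes shifted by `effect_size` noise standard deviations in
#' the disease group. Each planted gene's direction (up or down) is drawn
#' once; with `shared_planted = TRUE` (default) the same genes shift in the
#' same direction in both datasets, the structure a cross-dataset
#' meta-filter is meant to recover. Each sample (column) is median-centered
#' after the shifts are applied.
#'
#' @param n_genes number of genes.
#' @param n_normal,n_disease samples per group (each >= 2), same in both
#'   datasets.
#' @param planted_fraction fraction of genes with a true shift (ignored
#'   when `planted_genes` is given).
#' @param effect_size mean disease shift in units of `noise_sd`.
#' @param noise_sd Gaussian noise standard deviation on the log scale.
#' @param shared_planted same planted genes and signs in both datasets.
#' @param gene_names optional gene symbols (length `n_genes`); defaults to
#'   `G0001`, ...
#' @param planted_genes optional explicit planted gene symbols (must be a
#'   subset of the gene names).
#' @param seed integer seed; reproducible, caller's RNG untouched.
#' @return List with `a` and `b` (`expression_dataset`s), `planted`
#'   (character vector) and `signs` (named +1/-1 per planted gene).
#' @export
make_expression_pair <- function(n_genes = 2000L, n_normal = 20L,
                                 n_disease = 20L, planted_fraction = 0.1,
                                 effect_size = 2, noise_sd = 1,
                                 shared_planted = TRUE, gene_names = NULL,
                                 planted_genes = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, n_normal >= 2, n_disease >= 2,
            planted_fraction >= 0, planted_fraction <= 1, noise_sd > 0)
  if (is.null(gene_names)) {
    width <- max(4L, nchar(as.character(n_genes)))
    gene_names <- sprintf(paste0("G%0", width, "d"), seq_len(n_genes))
  }
  stopifnot(length(gene_names) == n_genes, !anyDuplicated(gene_names))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  if (is.null(planted_genes)) {
    n_planted <- floor(planted_fraction * n_genes)
    if (planted_fraction > 0 && n_planted < 1L) {
      warning("planted_fraction * n_genes < 1; no genes planted")
    }
    planted_genes <- if (n_planted >= 1L)
      sort(sample(gene_names, n_planted)) else character(0)
  } else {
    planted_genes <- sort(unique(as.character(planted_genes)))
    stopifnot(all(planted_genes %in% gene_names))
  }
  signs <- if (length(planted_genes)) {
    s <- sample(c(-1, 1), length(planted_genes), replace = TRUE)
    names(s) <- planted_genes
    s
  } else stats::setNames(numeric(0), character(0))

  one_dataset <- function(label, signs_here) {
    n_s <- n_normal + n_disease
    mat <- matrix(stats::rnorm(n_genes * n_s, sd = noise_sd),
                  nrow = n_genes, ncol = n_s,
                  dimnames = list(gene_names,
                                  sprintf("%s_s%02d", label, seq_len(n_s))))
    groups <- stats::setNames(rep(c("normal", "disease"),
                                  c(n_normal, n_disease)), colnames(mat))
    if (length(signs_here)) {
      dis <- which(groups == "disease")
      mat[names(signs_here), dis] <- mat[names(signs_here), dis] +
        signs_here * effect_size * noise_sd
    }
    mat <- sweep(mat, 2, apply(mat, 2, stats::median))
    expression_dataset(mat, groups, name = label)
  }
  signs_b <- if (shared_planted) signs else {
    s <- sample(c(-1, 1), length(signs), replace = TRUE)
    names(s) <- names(signs)
    s
  }
  list(a = one_dataset("cohortA", signs),
       b = one_dataset("cohortB", signs_b),
       planted = planted_genes, signs = signs)
}
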