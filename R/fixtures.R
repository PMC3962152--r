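#' Bundled NOTCH1-interactome hub gene list
#'
#' The 42 hub genes reported for the high-confidence NOTCH1
#' protein-interaction network in T-cell acute lymphoblastic leukemia
#' (common to the top-50 degree and top-50 betweenness rankings),
#' transcribed from the published study's hub table.
#'
#' @return Character vector of 42 gene symbols.
#' @export
notch1_hub_genes <- function() {
  path <- system.file("extdata", "notch1_hub_genes.tsv", package = "hubnet",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)$gene
}

#' Bundled published T-ALL differential-expression summary for hub genes
#'
#' Per-gene summaries (Oncomine gene-rank percentile, t-test p-value and
#' fold change) for NOTCH1-interactome hub genes in two published T-ALL
#' microarray cohorts (Andersson et al. as dataset a, Haferlach et al. as
#' dataset b), transcribed from the published study's expression table.
#' `printed_class` records the published under/over grouping; the
#' package recomputes the classification from the fold-change signs.
#'
#' @return Data frame with columns `gene`, `rank_pct_a`, `p_a`, `fc_a`,
#'   `rank_pct_b`, `p_b`, `fc_b`, `printed_class`.
#' @export
tall_hub_expression <- function() {
  path <- system.file("extdata", "tall_hub_expression.tsv",
                      package = "hubnet", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
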