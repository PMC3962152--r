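#' Construct a two-group expression dataset
#'
#' Expression values are assumed log-transformed and median-centered, the
#' Oncomine convention for microarray data; all statistics are computed on
#' that scale.
#'
#' @param matrix numeric genes x samples matrix with unique gene symbols as
#'   row names and sample ids as column names.
#' @param groups named character vector or two-column data frame mapping
#'   every sample to `"normal"` or `"disease"`.
#' @param name dataset label.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, groups, name = "dataset") {
  stopifnot(is.matrix(matrix), is.numeric(matrix),
            !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  if (anyDuplicated(rownames(matrix))) stop("gene symbols must be unique")
  if (is.data.frame(groups)) {
    g <- as.character(groups[[2]]); names(g) <- as.character(groups[[1]])
    groups <- g
  }
  if (!all(colnames(matrix) %in% names(groups)))
    stop("every sample must have a group label")
  groups <- groups[colnames(matrix)]
  if (!all(groups %in% c("normal", "disease")))
    stop("group labels must be 'normal' or 'disease'")
  if (sum(groups == "normal") < 2L || sum(groups == "disease") < 2L)
    stop("need at least 2 samples per group")
  structure(list(matrix = matrix, groups = groups, name = name),
            class = "expression_dataset")
}

#' Read an expression dataset from TSV files
#'
#' The matrix file has gene symbols in the first column and a header row of
#' sample ids; the groups file is a two-column TSV mapping sample id to
#' `normal`/`disease`.
#'
#' @param matrix_path,groups_path file paths.
#' @param name dataset label.
#' @return An `expression_dataset`.
#' @export
read_expression_dataset <- function(matrix_path, groups_path,
                                    name = basename(matrix_path)) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- as.character(raw[[1]])
  grp <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  expression_dataset(mat, grp, name = name)
}

#' Per-gene two-group differential statistics
#'
#' For every gene, the classical two-sample Student's t-test with pooled
#' variance (Welch's unequal-variance form behind `var_equal = FALSE`) and
#' a two-sided p-value. The fold change is the disease-minus-normal
#' difference of group means on the log scale, so a negative value means
#' underexpressed in disease. Genes are assigned to the `under` (negative)
#' or `over` (positive) direction class by the sign of that difference.
#'
#' Degenerate genes (zero pooled variance): equal group means give t = 0,
#' p = 1; unequal means give the smallest representable p with
#' `degenerate = TRUE`.
#'
#' @param ds an `expression_dataset`.
#' @param var_equal pooled-variance Student's t (default) or Welch.
#' @return Data frame with one row per gene: `gene`, `t_statistic`,
#'   `p_value`, `fold_change`, `direction` (`under`/`over`/`none`),
#'   `degenerate`, and `dataset`.
#' @export
differential_stats <- function(ds, var_equal = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  x <- ds$matrix[, ds$groups == "disease", drop = FALSE]
  y <- ds$matrix[, ds$groups == "normal", drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  fc <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(fc))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- fc / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se == 0
  zero_eq <- degenerate & fc == 0
  zero_ne <- degenerate & fc != 0
  tstat[zero_eq] <- 0; p[zero_eq] <- 1
  tstat[zero_ne] <- sign(fc[zero_ne]) * Inf
  p[zero_ne] <- .Machine$double.xmin
  data.frame(gene = rownames(ds$matrix),
             t_statistic = unname(tstat), p_value = unname(p),
             fold_change = unname(fc),
             direction = ifelse(fc < 0, "under",
                                ifelse(fc > 0, "over", "none")),
             degenerate = unname(zero_ne),
             dataset = ds$name, stringsAsFactors = FALSE)
}

#' Gene-rank percentiles within direction classes
#'
#' Within each direction class (under/over) of one dataset, genes are
#' ranked by ascending p-value (ties broken by gene symbol) and the rank is
#' expressed as a top-percentile, `ceiling(100 * rank / class size)` — the
#' Oncomine "gene rank" convention ("top 7%" means rank within the best 7%
#' of that class).
#'
#' @param stats data frame from [differential_stats()] (one dataset).
#' @return The input with `rank` and `rank_percentile` columns filled;
#'   genes with direction `none` get `NA` in both.
#' @export
rank_percentiles <- function(stats) {
  stopifnot(is.data.frame(stats),
            all(c("gene", "p_value", "direction") %in% names(stats)))
  stats$rank <- NA_integer_
  stats$rank_percentile <- NA_real_
  for (cls in c("under", "over")) {
    idx <- which(stats$direction == cls)
    if (!length(idx)) next
    ord <- idx[order(stats$p_value[idx], stats$gene[idx])]
    stats$rank[ord] <- seq_along(ord)
    stats$rank_percentile[ord] <- ceiling(100 * seq_along(ord) / length(ord))
  }
  stats
}

# shared meta-combination core: everything downstream of per-dataset
# percentiles, so computed and printed (published-table) inputs take the
# same path
meta_core <- function(gene, pct_a, fc_a, pct_b, fc_b,
                      threshold_pct, rule) {
  present <- !is.na(fc_a) & !is.na(fc_b)
  concordant <- present & (sign(fc_a) == sign(fc_b)) & fc_a != 0
  direction <- rep("absent", length(gene))
  direction[present & !concordant] <- "discordant"
  direction[concordant & fc_a < 0] <- "under"
  direction[concordant & fc_a > 0] <- "over"
  cumulative <- switch(rule,
    mean = (pct_a + pct_b) / 2,
    sum  = pct_a + pct_b,
    max  = pmax(pct_a, pct_b))
  cumulative[!present] <- NA_real_
  passes <- direction %in% c("under", "over") &
    !is.na(cumulative) & cumulative <= threshold_pct
  out <- data.frame(gene = gene,
                    rank_pct_a = pct_a, fold_change_a = fc_a,
                    rank_pct_b = pct_b, fold_change_b = fc_b,
                    direction = direction,
                    cumulative_percentile = cumulative,
                    passes_filter = passes, stringsAsFactors = FALSE)
  out <- out[order(out$cumulative_percentile, out$gene, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine differential statistics across two datasets
#'
#' The cross-dataset meta-filter: a gene is `absent` unless reported in
#' both datasets, `discordant` if its fold changes disagree in sign, and
#' otherwise takes the shared direction. Its cumulative gene-rank
#' percentile is by default the mean of the two per-dataset percentiles
#' (`sum` and `max` variants available), and it passes the filter when the
#' direction is concordant and the cumulative percentile is within the top
#' `threshold_pct` percent (study convention: 36).
#'
#' @param a,b outputs of [rank_percentiles()] for the two datasets.
#' @param threshold_pct cumulative-percentile cutoff (top X%).
#' @param rule cumulative-rank rule: `"mean"` (default), `"sum"`, `"max"`.
#' @return Data frame sorted by cumulative percentile: `gene`, per-dataset
#'   percentiles and fold changes, `direction`
#'   (`under`/`over`/`discordant`/`absent`), `cumulative_percentile`,
#'   `passes_filter`.
#' @export
meta_combine <- function(a, b, threshold_pct = 36,
                         rule = c("mean", "sum", "max")) {
  rule <- match.arg(rule)
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  genes <- sort(union(a$gene, b$gene))
  ia <- match(genes, a$gene); ib <- match(genes, b$gene)
  meta_core(genes,
            pct_a = a$rank_percentile[ia], fc_a = a$fold_change[ia],
            pct_b = b$rank_percentile[ib], fc_b = b$fold_change[ib],
            threshold_pct = threshold_pct, rule = rule)
}

#' Meta-filter records from a printed per-dataset summary table
#'
#' Applies the same cross-dataset combination as [meta_combine()] to a
#' table of already-computed per-dataset gene-rank percentiles and fold
#' changes, e.g. the bundled published T-ALL summary from
#' [tall_hub_expression()].
#'
#' @param tbl data frame with columns `gene`, `rank_pct_a`, `fc_a`,
#'   `rank_pct_b`, `fc_b`.
#' @inheritParams meta_combine
#' @return As [meta_combine()].
#' @export
meta_from_printed <- function(tbl, threshold_pct = 36,
                              rule = c("mean", "sum", "max")) {
  rule <- match.arg(rule)
  stopifnot(all(c("gene", "rank_pct_a", "fc_a", "rank_pct_b", "fc_b")
                %in% names(tbl)))
  meta_core(tbl$gene, tbl$rank_pct_a, tbl$fc_a, tbl$rank_pct_b, tbl$fc_b,
            threshold_pct = threshold_pct, rule = rule)
}

#' Classify hub genes by their meta-expression direction
#'
#' Restricts the meta-combined records to a hub gene set and partitions
#' them into under-/over-expressed, discordant, and absent tables; hub
#' genes with no record at all are reported as unmeasured.
#'
#' @param hubs character vector of hub gene symbols.
#' @param records data frame from [meta_combine()] or [meta_from_printed()].
#' @return An object of class `hub_expression_report`: list of data frames
#'   `under`, `over`, `discordant`, `absent`, character vector
#'   `unmeasured`, and a `counts` summary.
#' @export
classify_hub_expression <- function(hubs, records) {
  hubs <- unique(as.character(hubs))
  rec <- records[records$gene %in% hubs, , drop = FALSE]
  split_dir <- function(d) {
    out <- rec[rec$direction == d, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  parts <- list(under = split_dir("under"), over = split_dir("over"),
                discordant = split_dir("discordant"),
                absent = split_dir("absent"))
  parts$unmeasured <- sort(setdiff(hubs, rec$gene))
  parts$counts <- c(under = nrow(parts$under), over = nrow(parts$over),
                    discordant = nrow(parts$discordant),
                    absent = nrow(parts$absent),
                    unmeasured = length(parts$unmeasured))
  structure(parts, class = "hub_expression_report")
}

#' @export
print.hub_expression_report <- function(x, ...) {
  cat("hub expression classification:\n")
  print(x$counts)
  invisible(x)
}
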