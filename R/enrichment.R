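#' Build a gene-set collection
#'
#' @param sets named list of character vectors (category id -> member gene
#'   symbols); empty categories are rejected.
#' @param background character vector of background gene symbols; defaults
#'   to the union of all sets (the usual stand-in when no genome-wide
#'   reference list is supplied).
#' @param strict if `TRUE`, a category gene outside the background is an
#'   error; if `FALSE`, such genes are dropped from the category.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background = NULL, strict = TRUE) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) stop("gene-set categories must be non-empty")
  if (is.null(background)) {
    background <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    background <- sort(unique(as.character(background)))
    outside <- lapply(sets, setdiff, y = background)
    if (any(lengths(outside) > 0L)) {
      if (strict) {
        bad <- names(sets)[which(lengths(outside) > 0L)[1]]
        stop("category '", bad, "' contains genes outside the background; ",
             "use strict = FALSE to drop them")
      }
      sets <- lapply(sets, intersect, y = background)
      sets <- sets[lengths(sets) > 0L]
    }
  }
  structure(list(sets = sets, background = background),
            class = "gene_set_collection")
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-delimited convention of MSigDB/WebGestalt: one set per
#' line as `id <tab> description <tab> gene...`. Parsing is delegated to
#' [fgsea::gmtPathways()].
#'
#' @param path path to the GMT file.
#' @inheritParams gene_set_collection
#' @return A `gene_set_collection`.
#' @export
read_gmt_collection <- function(path, background = NULL, strict = TRUE) {
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets, background = background, strict = strict)
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' P(X >= observed overlap) where X is hypergeometric with population size
#' |background|, |category| successes, and |query| draws — the classical
#' over-representation test. Computed exactly via [stats::phyper()].
#'
#' @param query,category,background character vectors of gene symbols;
#'   `query` and `category` must be contained in `background` (with
#'   `strict = FALSE`, out-of-background genes are dropped first).
#' @param strict error on out-of-background genes instead of dropping them.
#' @return The upper-tail p-value in (0, 1].
#' @export
hypergeometric_test <- function(query, category, background, strict = TRUE) {
  query <- unique(as.character(query))
  category <- unique(as.character(category))
  background <- unique(as.character(background))
  if (strict) {
    if (length(setdiff(query, background)))
      stop("query contains genes outside the background")
    if (length(setdiff(category, background)))
      stop("category contains genes outside the background")
  } else {
    query <- intersect(query, background)
    category <- intersect(category, background)
  }
  ov <- length(intersect(query, category))
  stats::phyper(ov - 1L, m = length(category),
                n = length(background) - length(category),
                k = length(query), lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`; input order
#' is preserved and values are capped at 1.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  stopifnot(all(p_values > 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation enrichment of a query gene list
#'
#' Tests every category of the collection with the upper-tail
#' hypergeometric law. Categories overlapping the query in fewer than
#' `min_overlap` genes are excluded before multiple-testing adjustment
#' (the WebGestalt convention), BH adjustment runs over the remaining
#' categories, and a category is significant when the chosen p-value
#' (adjusted by default) is at most `alpha`.
#'
#' @param query character vector of gene symbols.
#' @param collection a `gene_set_collection`.
#' @param alpha significance cutoff (default 0.05).
#' @param min_overlap minimum query/category overlap to report (default 2).
#' @param alpha_on apply `alpha` to `"adjusted"` (default) or `"raw"`
#'   p-values.
#' @param strict passed to [hypergeometric_test()].
#' @return Data frame sorted by adjusted p then category id: `category`,
#'   `n_query`, `n_category`, `n_overlap`, `n_background`, `p_value`,
#'   `adjusted_p`, `significant`, plus `overlap_genes` (comma-separated).
#' @export
enrich <- function(query, collection, alpha = 0.05, min_overlap = 2L,
                   alpha_on = c("adjusted", "raw"), strict = TRUE) {
  alpha_on <- match.arg(alpha_on)
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  if (strict) {
    if (length(setdiff(query, collection$background)))
      stop("query contains genes outside the background")
  } else {
    query <- intersect(query, collection$background)
  }
  empty <- data.frame(category = character(), n_query = integer(),
                      n_category = integer(), n_overlap = integer(),
                      n_background = integer(), p_value = numeric(),
                      adjusted_p = numeric(), significant = logical(),
                      overlap_genes = character(), stringsAsFactors = FALSE)
  if (!length(query)) {
    warning("empty query gene list; returning no enrichment results")
    return(empty)
  }
  bg_n <- length(collection$background)
  rows <- lapply(names(collection$sets), function(id) {
    cat_genes <- collection$sets[[id]]
    ov <- sort(intersect(query, cat_genes))
    if (length(ov) < min_overlap) return(NULL)
    data.frame(category = id, n_query = length(query),
               n_category = length(cat_genes), n_overlap = length(ov),
               n_background = bg_n,
               p_value = stats::phyper(length(ov) - 1L, m = length(cat_genes),
                                       n = bg_n - length(cat_genes),
                                       k = length(query), lower.tail = FALSE),
               overlap_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out$significant <- (if (alpha_on == "adjusted") out$adjusted_p
                      else out$p_value) <= alpha
  out <- out[order(out$adjusted_p, out$category), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("category", "n_query", "n_category", "n_overlap", "n_background",
          "p_value", "adjusted_p", "significant", "overlap_genes")]
}
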