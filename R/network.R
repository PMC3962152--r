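#' Construct an interaction network from an edge table
#'
#' An `interaction_network` is a simple undirected graph whose nodes are
#' protein (gene) symbols and whose edges carry a confidence score in
#' \[0, 1\], the convention used by STRING combined scores. Construction
#' cleans the input: self-loops are dropped, duplicate unordered pairs are
#' collapsed keeping the maximum confidence, and nodes are stored in
#' lexicographic order so that all downstream output is deterministic.
#'
#' @param edges data frame with columns `protein_a`, `protein_b`,
#'   `confidence` (first three columns are used positionally).
#' @param nodes optional character vector of additional (possibly isolated)
#'   node symbols to retain.
#' @return An object of class `interaction_network`: a list with `nodes`
#'   (sorted character vector) and `edges` (data frame `protein_a`,
#'   `protein_b`, `confidence`, with `protein_a` < `protein_b`).
#' @export
interaction_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(protein_a = character(), protein_b = character(),
                        confidence = numeric())
  }
  stopifnot(is.data.frame(edges), ncol(edges) >= 3)
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  w <- as.numeric(edges[[3]])
  if (anyNA(w) || any(w < 0 | w > 1)) {
    stop("confidence scores must be numbers in [0, 1]")
  }
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("node symbols must be non-empty strings")
  }
  keep <- a != b                        # drop self-loops
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  if (length(lo)) {
    key <- paste(lo, hi, sep = "\r")
    w <- tapply(w, key, max)            # duplicate pairs keep max confidence
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    lo <- vapply(parts, `[`, character(1), 1L)
    hi <- vapply(parts, `[`, character(1), 2L)
  }
  edge_df <- data.frame(protein_a = lo, protein_b = hi,
                        confidence = as.numeric(w),
                        stringsAsFactors = FALSE)
  edge_df <- edge_df[order(edge_df$protein_a, edge_df$protein_b), ,
                     drop = FALSE]
  rownames(edge_df) <- NULL
  all_nodes <- sort(unique(c(edge_df$protein_a, edge_df$protein_b,
                             as.character(nodes))))
  structure(list(nodes = all_nodes, edges = edge_df),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Node and edge counts
#' @param net an `interaction_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Convert an interaction network to an igraph object
#'
#' @param net an `interaction_network`.
#' @param weighted attach the confidence score as the `weight` edge
#'   attribute (the confidence is always available as the `confidence`
#'   attribute).
#' @return An undirected [igraph::graph] with vertices in the network's
#'   lexicographic node order.
#' @export
as_igraph <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  if (weighted) igraph::E(g)$weight <- igraph::E(g)$confidence
  g
}

#' Read a weighted edge list in a STRING-export-style TSV dialect
#'
#' Expects columns `protein_a`, `protein_b`, `combined_score`. Two score
#' dialects are supported: `"unit"` (scores already in \[0, 1\]) and
#' `"string"` (integer combined scores in \[0, 1000\], divided by 1000 on
#' read, as in STRING's tab-separated exports). Lines starting with `#` are
#' skipped. The returned network is cleaned as by [interaction_network()].
#'
#' @param path path to the edge-list file.
#' @param score_scale `"unit"` or `"string"`.
#' @param delimiter field delimiter (default tab).
#' @param has_header whether the first non-comment line is a header row.
#' @return An `interaction_network`.
#' @export
read_edge_list <- function(path, score_scale = c("unit", "string"),
                           delimiter = "\t", has_header = TRUE) {
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (has_header && length(lines)) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  if (!length(lines)) return(interaction_network())
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed edge row at line %d: fewer than 3 columns",
                 line_no[bad[1]]))
  }
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(s)) {
    stop(sprintf("malformed score at line %d: not a number",
                 line_no[which(is.na(s))[1]]))
  }
  if (score_scale == "string") {
    out <- which(s < 0 | s > 1000 | s != round(s))
    if (length(out)) {
      stop(sprintf(
        "score out of range at line %d: string dialect requires integers in [0, 1000]",
        line_no[out[1]]))
    }
    s <- s / 1000
  } else {
    out <- which(s < 0 | s > 1)
    if (length(out)) {
      stop(sprintf("score out of range at line %d: unit dialect requires [0, 1]",
                   line_no[out[1]]))
    }
  }
  interaction_network(data.frame(protein_a = a, protein_b = b,
                                 confidence = s, stringsAsFactors = FALSE))
}

#' Write an interaction network as a TSV edge list
#'
#' Inverse of [read_edge_list()]; a write/read round-trip reproduces the
#' network exactly (unit dialect) or to 1/1000 (string dialect).
#'
#' @inheritParams read_edge_list
#' @param net an `interaction_network`.
#' @export
write_edge_list <- function(net, path, score_scale = c("unit", "string")) {
  score_scale <- match.arg(score_scale)
  stopifnot(inherits(net, "interaction_network"))
  out <- net$edges
  names(out)[3] <- "combined_score"
  if (score_scale == "string") out$combined_score <- round(out$combined_score * 1000)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter edges by confidence score
#'
#' Retains edges whose confidence exceeds `threshold` (strict inequality by
#' default, i.e. a 0.9 threshold keeps scores greater than 0.9 — the
#' high-confidence convention for STRING networks). Nodes left without any
#' edge are dropped by default, giving a displayed-interactors network.
#'
#' @param net an `interaction_network`.
#' @param threshold confidence cutoff in \[0, 1\].
#' @param strict if `TRUE` keep `confidence > threshold`, else `>=`.
#' @param keep_isolated retain nodes that lose all their edges.
#' @return The filtered `interaction_network`.
#' @export
filter_by_confidence <- function(net, threshold = 0.9, strict = TRUE,
                                 keep_isolated = FALSE) {
  stopifnot(inherits(net, "interaction_network"),
            threshold >= 0, threshold <= 1)
  keep <- if (strict) net$edges$confidence > threshold
          else net$edges$confidence >= threshold
  interaction_network(net$edges[keep, , drop = FALSE],
                      nodes = if (keep_isolated) net$nodes)
}

#' Induced subgraph on the largest connected component
#'
#' Ties in component size are broken by the component containing the
#' lexicographically smallest node, so the result is deterministic.
#'
#' @param net a non-empty `interaction_network`.
#' @return An `interaction_network` restricted to the largest component.
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (n_nodes(net) == 0L) stop("cannot take the largest component of an empty network")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  # nodes are in lexicographic order, so the first vertex whose component is
  # a candidate breaks the tie
  member <- comp$membership
  winner <- member[match(TRUE, member %in% cand)]
  keep_nodes <- net$nodes[member == winner]
  in_comp <- net$edges$protein_a %in% keep_nodes &
    net$edges$protein_b %in% keep_nodes
  interaction_network(net$edges[in_comp, , drop = FALSE], nodes = keep_nodes)
}
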