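#' Rank nodes by a centrality score
#'
#' Descending by the chosen score; ties broken lexicographically by node
#' symbol so the ranking is deterministic.
#'
#' @param table a centrality table as from [centrality_table()].
#' @param method `"degree"` or `"betweenness"`.
#' @return Character vector of node symbols, best first.
#' @export
rank_nodes <- function(table, method = c("degree", "betweenness")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table), nrow(table) > 0,
            all(c("node", method) %in% names(table)))
  table$node[order(-table[[method]], table$node)]
}

#' Select hub nodes by the degree/betweenness intersection rule
#'
#' Ranks all nodes by degree and by betweenness, truncates both rankings to
#' the top `n_top`, and returns the nodes common to both lists — the "common
#' hub" set used to prioritize genes for downstream expression analysis.
#'
#' @param net a non-empty `interaction_network`.
#' @param n_top size of each top list (the study convention is 50).
#' @param use_confidence_weights passed to [centrality_table()].
#' @return An object of class `hub_selection`: list with `top_by_degree`,
#'   `top_by_betweenness` (ordered), `common_hubs` (lexicographically
#'   sorted), `n_top`, and the underlying `centrality` table.
#' @export
select_hubs <- function(net, n_top = 50, use_confidence_weights = FALSE) {
  stopifnot(n_top >= 1)
  tab <- centrality_table(net, use_confidence_weights = use_confidence_weights)
  n_take <- min(n_top, nrow(tab))
  by_deg <- rank_nodes(tab, "degree")[seq_len(n_take)]
  by_btw <- rank_nodes(tab, "betweenness")[seq_len(n_take)]
  structure(list(top_by_degree = by_deg,
                 top_by_betweenness = by_btw,
                 common_hubs = sort(intersect(by_deg, by_btw)),
                 n_top = as.integer(n_top),
                 centrality = tab),
            class = "hub_selection")
}

#' @export
print.hub_selection <- function(x, ...) {
  cat(sprintf("hub selection (top %d by degree and betweenness): %d common hubs\n",
              x$n_top, length(x$common_hubs)))
  if (length(x$common_hubs)) {
    cat(strwrap(paste(x$common_hubs, collapse = " "), indent = 2, exdent = 2),
        sep = "\n")
  }
  invisible(x)
}

#' Tabulate hub membership for every node
#'
#' @param hubs a `hub_selection`.
#' @return Data frame: `node`, `degree`, `betweenness`, `in_degree_top`,
#'   `in_betweenness_top`, `is_common_hub`.
#' @export
hub_table <- function(hubs) {
  stopifnot(inherits(hubs, "hub_selection"))
  tab <- hubs$centrality
  tab$in_degree_top <- tab$node %in% hubs$top_by_degree
  tab$in_betweenness_top <- tab$node %in% hubs$top_by_betweenness
  tab$is_common_hub <- tab$node %in% hubs$common_hubs
  tab[order(-tab$degree, tab$node), , drop = FALSE]
}
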