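# Rule-network construction and GraphML serialisation.

# write via a temp file in the same directory, then rename: no partial
# output is ever left at `path` on error
write_atomic <- function(writer, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("cannot write output file: ", path)
  invisible(path)
}

#' Build the bipartite item/rule network
#'
#' The network-figure representation of a ranked rule table: one vertex per
#' distinct block (kind `"item"`) and one per rule (kind `"rule"`, carrying
#' `support` and `lift` as numeric attributes for downstream sizing and
#' colouring), with directed edges antecedent item -> rule vertex ->
#' consequent item. A rule vertex therefore has in-degree equal to its
#' antecedent size and out-degree 1. Item vertices are ordered
#' alphabetically, rule vertices by rank, so the construction is
#' deterministic.
#'
#' @param rules Ranked rule frame from [mine_subgroup()]; must be non-empty.
#' @return An [igraph][igraph::make_graph] directed graph.
#' @export
build_rule_graph <- function(rules) {
  if (nrow(rules) == 0L) stop("cannot build a graph from an empty rule list")
  ante <- strsplit(rules$antecedent, ",", fixed = TRUE)
  items <- sort(unique(c(unlist(ante), rules$consequent)), method = "radix")
  rule_ids <- sprintf("rule_%03d", seq_len(nrow(rules)))
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(items), name = items, kind = "item",
                            label = items, support = NA_real_,
                            lift = NA_real_)
  g <- igraph::add_vertices(
    g, length(rule_ids), name = rule_ids, kind = "rule",
    label = paste(rules$antecedent, "->", rules$consequent),
    support = rules$support, lift = rules$lift)
  edges <- character(0)
  for (i in seq_along(rule_ids)) {
    for (a in ante[[i]]) edges <- c(edges, a, rule_ids[i])
    edges <- c(edges, rule_ids[i], rules$consequent[i])
  }
  igraph::add_edges(g, edges)
}

#' Export a rule network as GraphML
#'
#' Vertex attributes written: `kind` (`"item"`/`"rule"`), `label`, `support`,
#' `lift`. The graph is validated first: every rule vertex must carry finite
#' support and lift, have out-degree 1 and in-degree >= 1, and no vertex may
#' dangle. Output is deterministic (two runs on the same input are
#' byte-identical) and written atomically.
#'
#' @param graph Graph from [build_rule_graph()].
#' @param path Output path.
#' @export
export_graph <- function(graph, path) {
  kind <- igraph::V(graph)$kind
  is_rule <- kind == "rule"
  sup <- igraph::V(graph)$support
  lft <- igraph::V(graph)$lift
  if (any(is_rule & (!is.finite(sup) | !is.finite(lft)))) {
    stop("rule vertex with missing support/lift attribute")
  }
  outdeg <- igraph::degree(graph, mode = "out")
  indeg <- igraph::degree(graph, mode = "in")
  if (any(is_rule & (outdeg != 1L | indeg < 1L))) {
    stop("rule vertex must have out-degree 1 and in-degree >= 1")
  }
  if (any(indeg + outdeg == 0L)) stop("dangling vertex in rule graph")
  write_atomic(function(p) {
    igraph::write_graph(graph, p, format = "graphml")
  }, path)
  invisible(path)
}
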