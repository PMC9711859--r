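#' Signed TF-to-target regulatory network
#'
#' A `RegulatoryNetwork` holds a directed, signed graph of transcription
#' factor (TF) to target-gene regulatory relationships, the container used
#' by every network stage of the pipeline. Edge sign +1 denotes activation
#' and -1 repression. Sources must be TF nodes, self-loops and duplicate
#' (source, target) pairs are rejected.
#'
#' @param edges data frame with columns `source`, `target` and `sign`
#'   (+1/-1). An `edge_id` column is derived as `"source->target"`.
#' @param tfs character vector of TF node ids. Defaults to the set of edge
#'   sources.
#' @param nodes optional character vector of all node ids (to retain
#'   isolated nodes); defaults to the union of edge endpoints and `tfs`.
#' @return an object of class `RegulatoryNetwork`: a list with elements
#'   `nodes` (data frame: `gene`, `is_tf`) and `edges` (data frame:
#'   `edge_id`, `source`, `target`, `sign`).
#' @examples
#' net <- regulatory_network(data.frame(source = "TF1", target = "G1", sign = 1))
#' net
#' @export
regulatory_network <- function(edges, tfs = NULL, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "sign") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges) > 0 && !all(edges$sign %in% c(-1L, 1L)))
    abort_aegrn("edge signs must be +1 or -1", "aegrn_invalid_parameter")
  if (any(edges$source == edges$target))
    abort_aegrn("self-loops are not allowed in a RegulatoryNetwork",
                "aegrn_invalid_parameter")
  key <- paste(edges$source, edges$target, sep = "->")
  if (anyDuplicated(key))
    abort_aegrn("duplicate (source, target) pairs in edge list",
                "aegrn_invalid_parameter")
  tfs <- unique(as.character(tfs %||% edges$source))
  if (nrow(edges) > 0 && !all(edges$source %in% tfs))
    abort_aegrn("all edge sources must be TF nodes", "aegrn_invalid_parameter")
  all_nodes <- unique(c(tfs, as.character(nodes), edges$source, edges$target))
  net <- list(
    nodes = data.frame(gene = all_nodes, is_tf = all_nodes %in% tfs,
                       stringsAsFactors = FALSE),
    edges = data.frame(edge_id = key, source = edges$source,
                       target = edges$target, sign = edges$sign,
                       stringsAsFactors = FALSE)
  )
  class(net) <- "RegulatoryNetwork"
  net
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork: %d nodes (%d TFs), %d edges (%d repressive)\n",
              nrow(x$nodes), sum(x$nodes$is_tf), nrow(x$edges),
              sum(x$edges$sign < 0)))
  invisible(x)
}

#' Number of nodes and edges of a network
#' @param network a `RegulatoryNetwork`.
#' @return named integer vector with elements `nodes`, `tfs`, `edges`.
#' @export
network_size <- function(network) {
  stopifnot(inherits(network, "RegulatoryNetwork"))
  c(nodes = nrow(network$nodes), tfs = sum(network$nodes$is_tf),
    edges = nrow(network$edges))
}

#' Convert a RegulatoryNetwork to an igraph graph
#'
#' Used for reachability checks and as an independent route in tests; edge
#' `sign` is carried as an edge attribute.
#'
#' @param network a `RegulatoryNetwork`.
#' @return an `igraph` directed graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "RegulatoryNetwork"))
  igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "sign")],
    directed = TRUE, vertices = network$nodes$gene)
}

# in/out-degree of every node, in node order
network_degrees <- function(network) {
  out_deg <- table(factor(network$edges$source, levels = network$nodes$gene))
  in_deg <- table(factor(network$edges$target, levels = network$nodes$gene))
  data.frame(gene = network$nodes$gene,
             out_degree = as.integer(out_deg),
             in_degree = as.integer(in_deg),
             stringsAsFactors = FALSE)
}
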