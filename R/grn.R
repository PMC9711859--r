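#' Build the master GRN restricted to responsive genes
#'
#' Integrates a curated signed TF-to-target edge list with the set of
#' genes differentially responsive in the temporal transcriptome: only
#' edges whose source and target are both responsive are kept, and nodes
#' left without any edge are dropped.
#'
#' @param tf_tg_edges a `RegulatoryNetwork` or a data frame with columns
#'   `source`, `target`, `sign`.
#' @param responsive_genes character vector of responsive gene ids.
#' @return a `RegulatoryNetwork` induced on the responsive genes.
#' @export
build_master_grn <- function(tf_tg_edges, responsive_genes) {
  net <- if (inherits(tf_tg_edges, "RegulatoryNetwork")) tf_tg_edges else
    regulatory_network(tf_tg_edges)
  keep <- net$edges$source %in% responsive_genes &
    net$edges$target %in% responsive_genes
  edges <- net$edges[keep, c("source", "target", "sign")]
  tfs <- intersect(net$nodes$gene[net$nodes$is_tf],
                   unique(edges$source))
  regulatory_network(edges, tfs = tfs)
}

#' Stratify a network by marker group
#'
#' Node counts per class/subtype, and edge counts per group under one of
#' two rules: `"target"` assigns each edge to its target node's group (a
#' partition: group edge counts sum to the total edge count), `"either"`
#' counts an edge for every group either endpoint belongs to (overlapping,
#' so counts may exceed the total).
#'
#' @param network a `RegulatoryNetwork`.
#' @param annotation data frame from [annotate_genes()] covering every
#'   network node.
#' @param rule `"target"` (default) or `"either"`.
#' @param level `"class"` or `"subtype"` (subtype stratifies the neuron
#'   class members only).
#' @return list with `node_counts` and `edge_counts` (named integer
#'   vectors by group label) and the `rule` used.
#' @export
stratify_network <- function(network, annotation, rule = c("target", "either"),
                             level = c("class", "subtype")) {
  rule <- match.arg(rule)
  level <- match.arg(level)
  stopifnot(inherits(network, "RegulatoryNetwork"))
  miss <- setdiff(network$nodes$gene, annotation$gene)
  if (length(miss))
    abort_aegrn(sprintf("nodes lacking annotation: %s",
                        paste(utils::head(miss, 5), collapse = ", ")),
                "aegrn_annotation_gap")
  grp <- annotation[[level]][match(network$nodes$gene, annotation$gene)]
  names(grp) <- network$nodes$gene
  labels <- unique(c(setdiff(unique(grp), "UNASSIGNED"), "UNASSIGNED"))
  node_counts <- vapply(labels, function(l) sum(grp == l), integer(1))
  ec <- if (rule == "target") {
    tg <- grp[network$edges$target]
    vapply(labels, function(l) sum(tg == l), integer(1))
  } else {
    sg <- grp[network$edges$source]
    tg <- grp[network$edges$target]
    vapply(labels, function(l) sum(sg == l | tg == l), integer(1))
  }
  list(node_counts = node_counts, edge_counts = ec, rule = rule,
       level = level)
}

#' Per-node temporal status series for one condition
#'
#' Extracts from a DE status table the trichotomous status of each gene at
#' each timepoint under one condition, plus each gene's first-response
#' timepoint (earliest non-NEUTRAL status).
#'
#' @param status_table a [de_status_table()].
#' @param condition condition label.
#' @param timepoints ordered timepoints.
#' @return a `NodeStateSeries`: list with `status` (character matrix,
#'   genes x timepoints), `first_response` (named integer index into
#'   `timepoints`, `NA` for never-responsive genes), `first_status`
#'   (status at first response), `condition` and `timepoints`.
#' @export
node_states <- function(status_table, condition, timepoints) {
  sub <- status_table[status_table$condition == condition &
                        status_table$timepoint %in% timepoints, ]
  if (nrow(sub) == 0L)
    abort_aegrn(sprintf("condition '%s' not present in status table", condition),
                "aegrn_missing_group")
  genes <- sort(unique(sub$gene))
  mat <- matrix(NA_character_, length(genes), length(timepoints),
                dimnames = list(genes, as.character(timepoints)))
  mat[cbind(match(sub$gene, genes), match(sub$timepoint, timepoints))] <-
    sub$status
  if (anyNA(mat))
    abort_aegrn("incomplete status series for some gene/timepoint",
                "aegrn_incomplete_series")
  fr <- apply(mat, 1, function(s) {
    i <- which(s != "NEUTRAL")
    if (length(i)) i[1] else NA_integer_
  })
  fs <- ifelse(is.na(fr), "NEUTRAL", mat[cbind(seq_along(fr), fr)])
  names(fs) <- genes
  out <- list(status = mat, first_response = fr, first_status = fs,
              condition = condition, timepoints = timepoints)
  class(out) <- "NodeStateSeries"
  out
}

#' @export
print.NodeStateSeries <- function(x, ...) {
  cat(sprintf("NodeStateSeries (%s): %d genes, %d responsive, timepoints %s\n",
              x$condition, nrow(x$status), sum(!is.na(x$first_response)),
              paste(x$timepoints, collapse = ", ")))
  invisible(x)
}

#' Is an edge transcriptionally coherent ("active")?
#'
#' An edge is active when both endpoints are differentially responsive and
#' the regulatory sign is coherent with their statuses: an activating edge
#' (+1) requires concordant statuses (UP,UP) or (DOWN,DOWN); a repressive
#' edge (-1) requires discordant statuses (UP,DOWN) or (DOWN,UP). Any
#' NEUTRAL endpoint makes the edge inactive. Equivalently, active iff
#' `sign * s(source) * s(target) == +1` with `s(UP)=+1, s(DOWN)=-1,
#' s(NEUTRAL)=0`. Set `up_only = TRUE` to restrict coherence to
#' up-regulated sources (activation cascades only).
#'
#' @param source_status,target_status character vectors of statuses in
#'   `{"UP","DOWN","NEUTRAL"}` (recycled to common length).
#' @param sign integer vector of edge signs (+1/-1).
#' @param up_only if `TRUE`, additionally require the source to be UP.
#' @return logical vector.
#' @examples
#' is_active_edge("UP", "UP", 1)       # TRUE
#' is_active_edge("UP", "DOWN", -1)    # TRUE: repression propagated
#' is_active_edge("NEUTRAL", "UP", 1)  # FALSE: unresponsive source
#' @export
is_active_edge <- function(source_status, target_status, sign,
                           up_only = FALSE) {
  ok <- status_to_sign(source_status) * status_to_sign(target_status) *
    as.integer(sign) == 1L
  if (up_only) ok <- ok & source_status == "UP"
  ok
}

#' Evaluate the active-edge set of a network at one timepoint
#'
#' @param network a `RegulatoryNetwork`.
#' @param states a [node_states()] series covering all network nodes.
#' @param timepoint one of `states$timepoints`, or `"any"` for the
#'   cumulative mode (an edge is active if coherent at any timepoint).
#' @param up_only passed to [is_active_edge()].
#' @return an `ActiveEdgeSet`: list with `condition`, `timepoint` and
#'   `edge_ids` (character vector).
#' @export
evaluate_active_edges <- function(network, states, timepoint,
                                  up_only = FALSE) {
  stopifnot(inherits(network, "RegulatoryNetwork"),
            inherits(states, "NodeStateSeries"))
  miss <- setdiff(c(network$edges$source, network$edges$target),
                  rownames(states$status))
  if (length(miss))
    abort_aegrn(sprintf("states missing for %d network node(s), e.g. %s",
                        length(miss), miss[1]),
                "aegrn_incomplete_series")
  active_at <- function(tp) {
    st <- states$status[, as.character(tp)]
    is_active_edge(st[network$edges$source], st[network$edges$target],
                   network$edges$sign, up_only = up_only)
  }
  act <- if (identical(timepoint, "any")) {
    Reduce(`|`, lapply(states$timepoints, active_at))
  } else {
    if (!timepoint %in% states$timepoints)
      abort_aegrn(sprintf("timepoint %s not in state series", timepoint),
                  "aegrn_incomplete_series")
    active_at(timepoint)
  }
  out <- list(condition = states$condition, timepoint = timepoint,
              edge_ids = network$edges$edge_id[act])
  class(out) <- "ActiveEdgeSet"
  out
}

#' @export
print.ActiveEdgeSet <- function(x, ...) {
  cat(sprintf("ActiveEdgeSet (%s, d%s): %d edges\n",
              x$condition, x$timepoint, length(x$edge_ids)))
  invisible(x)
}

#' Fraction of active edges, overall or within one marker group
#'
#' @param active an [evaluate_active_edges()] result.
#' @param network the `RegulatoryNetwork` the set was evaluated on.
#' @param group `"ALL"` (default) or a group label present in
#'   `annotation`.
#' @param annotation [annotate_genes()] output; required when `group` is
#'   not `"ALL"`.
#' @param rule edge-group rule, `"target"` or `"either"` (see
#'   [stratify_network()]).
#' @param level `"class"` or `"subtype"`.
#' @return fraction in `[0, 1]`; `NA` (with a warning) when the group has
#'   no edges.
#' @export
active_edge_fraction <- function(active, network, group = "ALL",
                                 annotation = NULL,
                                 rule = c("target", "either"),
                                 level = c("class", "subtype")) {
  rule <- match.arg(rule)
  level <- match.arg(level)
  stopifnot(inherits(active, "ActiveEdgeSet"),
            inherits(network, "RegulatoryNetwork"))
  edges <- network$edges
  if (!identical(group, "ALL")) {
    if (is.null(annotation))
      abort_aegrn("`annotation` required for group-wise fractions",
                  "aegrn_invalid_parameter")
    grp <- annotation[[level]][match(network$nodes$gene, annotation$gene)]
    names(grp) <- network$nodes$gene
    in_group <- if (rule == "target") grp[edges$target] == group else
      grp[edges$source] == group | grp[edges$target] == group
    edges <- edges[in_group, ]
  }
  if (nrow(edges) == 0L) {
    warning(sprintf("group '%s' has no edges; fraction undefined", group))
    return(NA_real_)
  }
  sum(edges$edge_id %in% active$edge_ids) / nrow(edges)
}
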