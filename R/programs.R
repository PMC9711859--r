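#' Intersect active-edge sets
#'
#' @param sets non-empty list of `ActiveEdgeSet` objects (or bare
#'   character vectors of edge ids).
#' @return character vector: edge ids present in every set.
#' @export
intersect_active_sets <- function(sets) {
  if (!is.list(sets) || length(sets) == 0L)
    abort_aegrn("`sets` must be a non-empty list", "aegrn_invalid_parameter")
  ids <- lapply(sets, function(s)
    if (inherits(s, "ActiveEdgeSet")) s$edge_ids else as.character(s))
  Reduce(intersect, ids)
}

#' Derive receptor-specific, common and inhibited programs by set algebra
#'
#' Given the active-edge sets of the three RARalpha-agonist conditions
#' (wild type plus the two non-alpha receptor knockouts), of the
#' "blocked" condition (wild type under combined RARbeta+gamma agonists)
#' and of the "rescue" condition (RARalpha-null under the same combined
#' agonists), computes:
#' \itemize{
#'   \item `alpha_specific`: edges active in all three alpha-agonist
#'     conditions;
#'   \item `common`: alpha-specific edges also active in the blocked
#'     condition (driven by either route);
#'   \item `inhibited`: alpha-specific edges silent in the blocked
#'     condition but reactivated in the rescue condition — the program
#'     held off by the unliganded RARalpha receptor;
#'   \item `residual`: remaining alpha-specific edges (neither common nor
#'     reactivated).
#' }
#' With `require_rescue = FALSE` the laxer variant
#' `inhibited = alpha_specific \ blocked` is used and `residual` is empty.
#'
#' @param alpha_sets list of `ActiveEdgeSet`s (the alpha-agonist
#'   conditions).
#' @param blocked_set `ActiveEdgeSet` of the blocked condition.
#' @param rescue_set `ActiveEdgeSet` of the rescue condition.
#' @param network optional `RegulatoryNetwork`; when given, all edge ids
#'   are checked against it.
#' @param require_rescue require reactivation in the rescue condition for
#'   an edge to count as inhibited (default `TRUE`).
#' @return a `ProgramPartition`: list of edge-id sets `alpha_specific`,
#'   `common`, `inhibited`, `residual`, plus `provenance`.
#' @export
derive_programs <- function(alpha_sets, blocked_set, rescue_set,
                            network = NULL, require_rescue = TRUE) {
  alpha_specific <- intersect_active_sets(alpha_sets)
  bl <- if (inherits(blocked_set, "ActiveEdgeSet")) blocked_set$edge_ids else
    as.character(blocked_set)
  rs <- if (inherits(rescue_set, "ActiveEdgeSet")) rescue_set$edge_ids else
    as.character(rescue_set)
  if (!is.null(network)) {
    stray <- setdiff(c(alpha_specific, bl, rs), network$edges$edge_id)
    if (length(stray))
      abort_aegrn(sprintf("edge ids absent from network, e.g. %s", stray[1]),
                  "aegrn_incompatible_universe")
  }
  common <- intersect(alpha_specific, bl)
  inhibited <- if (require_rescue)
    setdiff(intersect(alpha_specific, rs), bl)
  else setdiff(alpha_specific, bl)
  residual <- setdiff(alpha_specific, union(common, inhibited))
  out <- list(alpha_specific = alpha_specific, common = common,
              inhibited = inhibited, residual = residual,
              provenance = list(
                alpha = vapply(alpha_sets, function(s)
                  if (inherits(s, "ActiveEdgeSet")) s$condition else NA_character_,
                  character(1)),
                blocked = if (inherits(blocked_set, "ActiveEdgeSet"))
                  blocked_set$condition else NA_character_,
                rescue = if (inherits(rescue_set, "ActiveEdgeSet"))
                  rescue_set$condition else NA_character_,
                require_rescue = require_rescue))
  class(out) <- "ProgramPartition"
  out
}

#' @export
print.ProgramPartition <- function(x, ...) {
  cat(sprintf(paste0("ProgramPartition: alpha-specific %d | common %d | ",
                     "inhibited %d | residual %d\n"),
              length(x$alpha_specific), length(x$common),
              length(x$inhibited), length(x$residual)))
  invisible(x)
}

#' Gene and TF composition of each program, with pairwise overlaps
#'
#' A program's gene set is the union of its edges' endpoints; its TF set
#' the union of edge sources. Programs are edge-granular; these are
#' derived views.
#'
#' @param partition a [derive_programs()] result.
#' @param network the `RegulatoryNetwork` the programs live on.
#' @return list with `genes` and `tfs` (named lists of character vectors
#'   per program) and `overlap` (named list of data frames of pairwise
#'   gene/TF overlap counts).
#' @export
program_gene_tf_sets <- function(partition, network) {
  stopifnot(inherits(partition, "ProgramPartition"),
            inherits(network, "RegulatoryNetwork"))
  progs <- c("alpha_specific", "common", "inhibited", "residual")
  ed <- network$edges
  stray <- setdiff(unlist(partition[progs], use.names = FALSE), ed$edge_id)
  if (length(stray))
    abort_aegrn(sprintf("program edge ids absent from network, e.g. %s",
                        stray[1]), "aegrn_incompatible_universe")
  genes <- lapply(partition[progs], function(ids) {
    e <- ed[ed$edge_id %in% ids, ]
    sort(unique(c(e$source, e$target)))
  })
  tfs <- lapply(partition[progs], function(ids)
    sort(unique(ed$source[ed$edge_id %in% ids])))
  pairs <- utils::combn(progs, 2, simplify = FALSE)
  overlap <- do.call(rbind, lapply(pairs, function(p) data.frame(
    program_a = p[1], program_b = p[2],
    gene_overlap = length(intersect(genes[[p[1]]], genes[[p[2]]])),
    tf_overlap = length(intersect(tfs[[p[1]]], tfs[[p[2]]])),
    stringsAsFactors = FALSE)))
  list(genes = genes, tfs = tfs, overlap = overlap)
}

#' Induced subnetwork on a gene set, optionally filtered by promoter state
#'
#' @param network a `RegulatoryNetwork`.
#' @param genes gene ids to keep.
#' @param state_filter optional predicate: a function of a gene id vector
#'   returning a logical keep-vector (e.g. a promoter-state lookup); only
#'   genes passing it are retained.
#' @param strict if `TRUE`, unknown gene ids raise an error; otherwise a
#'   warning listing them is issued and they are dropped.
#' @return the induced `RegulatoryNetwork` (edges kept iff both endpoints
#'   kept).
#' @export
subset_network <- function(network, genes, state_filter = NULL,
                           strict = FALSE) {
  stopifnot(inherits(network, "RegulatoryNetwork"))
  genes <- as.character(genes)
  unknown <- setdiff(genes, network$nodes$gene)
  if (length(unknown)) {
    msg <- sprintf("%d gene id(s) not in network, e.g. %s",
                   length(unknown), unknown[1])
    if (strict) abort_aegrn(msg, "aegrn_unknown_gene") else warning(msg)
    genes <- setdiff(genes, unknown)
  }
  if (!is.null(state_filter)) genes <- genes[state_filter(genes)]
  keep <- network$edges$source %in% genes & network$edges$target %in% genes
  edges <- network$edges[keep, c("source", "target", "sign")]
  tfs <- intersect(network$nodes$gene[network$nodes$is_tf], genes)
  if (nrow(edges) == 0L)
    return(regulatory_network(
      data.frame(source = character(), target = character(),
                 sign = integer(), stringsAsFactors = FALSE),
      tfs = tfs, nodes = genes))
  regulatory_network(edges, tfs = tfs, nodes = genes)
}
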