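#' Edges a transcription-regulatory cascade may traverse
#'
#' An edge u -> v is traversable when (i) it is coherent ("active") at the
#' endpoints' first-response statuses and (ii) the target does not respond
#' before the source (`first_response(v) >= first_response(u)`), so that
#' cascades respect temporal causality. Set `temporal = FALSE` to drop
#' rule (ii) for sensitivity analysis.
#'
#' @param network a `RegulatoryNetwork`.
#' @param states a [node_states()] series covering the network nodes.
#' @param temporal enforce temporal ordering (default `TRUE`).
#' @return the subset of `network$edges` that cascades may cross.
#' @keywords internal
cascade_edges <- function(network, states, temporal = TRUE) {
  ed <- network$edges
  fr <- states$first_response
  fs <- states$first_status
  miss <- setdiff(c(ed$source, ed$target), names(fr))
  if (length(miss))
    abort_aegrn(sprintf("states missing for node %s", miss[1]),
                "aegrn_incomplete_series")
  ok <- !is.na(fr[ed$source]) & !is.na(fr[ed$target]) &
    is_active_edge(fs[ed$source], fs[ed$target], ed$sign)
  if (temporal) {
    ok[is.na(ok)] <- FALSE
    both <- ok
    ok[both] <- fr[ed$target[both]] >= fr[ed$source[both]]
  }
  ed[which(ok), ]
}

#' Simulate a transcription-regulatory cascade from one TF
#'
#' Breadth-first propagation from `start_tf` across coherent,
#' temporally ordered edges (see [cascade_edges()]); models the spread of
#' a regulatory signal through the reconstructed GRN.
#'
#' @param network a `RegulatoryNetwork`.
#' @param states a [node_states()] series.
#' @param start_tf a responsive TF node id.
#' @param temporal enforce temporal ordering (default `TRUE`).
#' @return character vector of all genes reached, excluding `start_tf`.
#' @export
propagate_cascade <- function(network, states, start_tf, temporal = TRUE) {
  stopifnot(inherits(network, "RegulatoryNetwork"))
  node_row <- match(start_tf, network$nodes$gene)
  if (is.na(node_row) || !network$nodes$is_tf[node_row])
    abort_aegrn(sprintf("'%s' is not a TF node of the network", start_tf),
                "aegrn_invalid_start")
  if (is.na(states$first_response[start_tf]))
    abort_aegrn(sprintf("'%s' is NEUTRAL at all timepoints; cascades need a responsive seed",
                        start_tf), "aegrn_invalid_start")
  ed <- cascade_edges(network, states, temporal = temporal)
  adj <- split(ed$target, ed$source)
  reached <- character(0)
  seen <- structure(logical(nrow(network$nodes)),
                    names = network$nodes$gene)
  seen[start_tf] <- TRUE
  frontier <- start_tf
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    if (!length(nxt)) break
    seen[nxt] <- TRUE
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  sort(reached)
}

#' Master regulatory index of a TF
#'
#' The fraction of responsive network genes that a TF can reach through
#' coherent, temporally ordered regulatory cascades; the seed TF is
#' excluded from the denominator:
#' `MRI = |cascade(tf)| / (n_responsive - 1)`.
#'
#' @inheritParams propagate_cascade
#' @param tf a responsive TF node id.
#' @return fraction in `[0, 1]`.
#' @export
master_regulatory_index <- function(network, states, tf, temporal = TRUE) {
  resp <- intersect(network$nodes$gene,
                    names(states$first_response)[!is.na(states$first_response)])
  if (length(resp) < 2L)
    abort_aegrn("MRI undefined: fewer than 2 responsive nodes in network",
                "aegrn_undefined_mri")
  length(propagate_cascade(network, states, tf, temporal = temporal)) /
    (length(resp) - 1L)
}

#' Degree-preserving randomization of a signed network
#'
#' Double-edge-swap rewiring: repeatedly picks two edges (a -> b, c -> d)
#' and exchanges their targets to (a -> d, c -> b), keeping each edge's
#' sign attached to it. Every node's in- and out-degree and the multiset
#' of edge signs are preserved exactly; swaps creating self-loops or
#' duplicate (source, target) pairs are rejected.
#'
#' @param network a `RegulatoryNetwork`.
#' @param n_swaps number of attempted swaps; default 10 x the edge count.
#' @param seed integer RNG seed.
#' @return a rewired `RegulatoryNetwork` over the same nodes.
#' @export
randomize_network <- function(network, n_swaps = NULL, seed = 1L) {
  stopifnot(inherits(network, "RegulatoryNetwork"))
  ed <- network$edges
  n_e <- nrow(ed)
  n_swaps <- assert_count(n_swaps %||% (10L * n_e), "n_swaps")
  if (n_e < 2L) {
    warning("network too small to swap; returning input unchanged")
    return(network)
  }
  src <- ed$source; tgt <- ed$target; sgn <- ed$sign
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (k in paste0(src, "->", tgt)) assign(k, TRUE, envir = seen)
  withr::with_seed(seed, {
    picks <- matrix(sample.int(n_e, 2L * n_swaps, replace = TRUE),
                    ncol = 2L)
    for (s in seq_len(n_swaps)) {
      i <- picks[s, 1L]; j <- picks[s, 2L]
      if (i == j) next
      a <- src[i]; b <- tgt[i]; c_ <- src[j]; d <- tgt[j]
      if (a == d || c_ == b || b == d) next
      new1 <- paste0(a, "->", d); new2 <- paste0(c_, "->", b)
      old1 <- paste0(a, "->", b); old2 <- paste0(c_, "->", d)
      rm(list = c(old1, old2), envir = seen)
      if (exists(new1, envir = seen, inherits = FALSE) ||
          exists(new2, envir = seen, inherits = FALSE)) {
        assign(old1, TRUE, envir = seen)
        assign(old2, TRUE, envir = seen)
        next
      }
      assign(new1, TRUE, envir = seen)
      assign(new2, TRUE, envir = seen)
      tgt[i] <- d; tgt[j] <- b
    }
  })
  regulatory_network(
    data.frame(source = src, target = tgt, sign = sgn,
               stringsAsFactors = FALSE),
    tfs = network$nodes$gene[network$nodes$is_tf],
    nodes = network$nodes$gene)
}

#' Empirical p-value against a null sample
#'
#' Add-one corrected upper-tail p-value,
#' `p = (1 + #\{null >= observed\}) / (1 + N)`, never exactly zero.
#'
#' @param observed_mri observed statistic.
#' @param null_mris numeric vector of null statistics (length >= 1).
#' @return p-value in `(0, 1]`.
#' @examples
#' empirical_pvalue(0.9, runif(99, 0, 0.5))  # 0.01
#' @export
empirical_pvalue <- function(observed_mri, null_mris) {
  if (length(null_mris) < 1L)
    abort_aegrn("null sample must be non-empty", "aegrn_invalid_parameter")
  (1 + sum(null_mris >= observed_mri)) / (1 + length(null_mris))
}

#' Rank TFs by master regulatory index with a randomized-network null
#'
#' Computes the MRI of every responsive TF on the observed network, then
#' re-computes each TF's MRI on `n_null` degree- and sign-preserving
#' randomizations of the wiring (node states held fixed), yielding
#' per-TF null summaries and empirical p-values. TFs are ranked by
#' descending MRI, ties broken lexicographically by gene id; `selected`
#' flags TFs with MRI strictly above `mri_cutoff`.
#'
#' @param network a `RegulatoryNetwork`.
#' @param states a [node_states()] series.
#' @param mri_cutoff selection cutoff in `[0, 1]`; default 0.7 (the
#'   conventional "master regulator" bar).
#' @param n_null number of randomized networks; default 100. Use 0 to
#'   skip the null (p-values `NA`).
#' @param n_swaps swap attempts per randomization; default 10 x edges.
#' @param seed integer seed driving all randomizations.
#' @param temporal enforce temporal ordering in cascades.
#' @return an `MRIRanking`: data frame with columns `tf`, `mri`,
#'   `null_mean`, `null_sd`, `p_value`, `rank`, `selected`, ordered by
#'   rank.
#' @export
rank_master_regulators <- function(network, states, mri_cutoff = 0.7,
                                   n_null = 100, n_swaps = NULL, seed = 1L,
                                   temporal = TRUE) {
  assert_fraction(mri_cutoff, "mri_cutoff")
  n_null <- assert_count(n_null, "n_null")
  resp <- names(states$first_response)[!is.na(states$first_response)]
  tfs <- sort(intersect(network$nodes$gene[network$nodes$is_tf], resp))
  if (length(tfs) == 0L)
    abort_aegrn("no responsive TF in network", "aegrn_invalid_start")
  mri_all <- function(net) vapply(
    tfs, function(tf) master_regulatory_index(net, states, tf,
                                              temporal = temporal),
    numeric(1))
  mri <- mri_all(network)
  if (n_null > 0L) {
    null_mat <- vapply(seq_len(n_null), function(r)
      mri_all(randomize_network(network, n_swaps = n_swaps,
                                seed = sub_seed(seed, r))),
      numeric(length(tfs)))
    null_mat <- matrix(null_mat, nrow = length(tfs))
    null_mean <- rowMeans(null_mat)
    null_sd <- apply(null_mat, 1, stats::sd)
    p_value <- vapply(seq_along(tfs), function(i)
      empirical_pvalue(mri[i], null_mat[i, ]), numeric(1))
  } else {
    null_mean <- null_sd <- p_value <- rep(NA_real_, length(tfs))
  }
  ord <- order(-mri, tfs)
  out <- data.frame(tf = tfs[ord], mri = mri[ord],
                    null_mean = null_mean[ord], null_sd = null_sd[ord],
                    p_value = p_value[ord], rank = seq_along(ord),
                    selected = mri[ord] > mri_cutoff,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("MRIRanking", "data.frame")
  out
}
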