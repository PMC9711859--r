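# Shared fixtures and independent oracles, built in code.

# Network from a compact edge spec: each element "SRC +TGT" / "SRC -TGT".
toy_network <- function(..., tfs = NULL, nodes = NULL) {
  spec <- c(...)
  parts <- strsplit(spec, " ", fixed = TRUE)
  regulatory_network(data.frame(
    source = vapply(parts, `[`, character(1), 1),
    target = sub("^[+-]", "", vapply(parts, `[`, character(1), 2)),
    sign = ifelse(startsWith(vapply(parts, `[`, character(1), 2), "-"),
                  -1L, 1L),
    stringsAsFactors = FALSE), tfs = tfs, nodes = nodes)
}

# DEStatusTable-shaped long data frame from a gene x timepoint status
# matrix for one condition; log2fc is filled consistently with status.
toy_status_table <- function(status_mat, condition = "WT:ATRA",
                             timepoints = as.numeric(colnames(status_mat)),
                             threshold = 2) {
  genes <- rownames(status_mat)
  rows <- expand.grid(gene = genes, timepoint = timepoints,
                      stringsAsFactors = FALSE)
  rows$condition <- condition
  rows$status <- status_mat[cbind(rows$gene, as.character(rows$timepoint))]
  rows$log2fc <- c(UP = threshold + 1, NEUTRAL = 0,
                   DOWN = -threshold - 1)[rows$status]
  rows <- rows[, c("gene", "condition", "timepoint", "log2fc", "status")]
  attr(rows, "threshold_log2") <- threshold
  class(rows) <- c("DEStatusTable", "data.frame")
  rows
}

toy_states <- function(status_mat, condition = "WT:ATRA") {
  node_states(toy_status_table(status_mat, condition), condition,
              as.numeric(colnames(status_mat)))
}

status_matrix <- function(genes, timepoints, default = "NEUTRAL") {
  matrix(default, length(genes), length(timepoints),
         dimnames = list(genes, as.character(timepoints)))
}

# Exhaustive hand enumeration of the active-edge rule: the only coherent
# combinations are concordant endpoints on activating edges and
# discordant endpoints on repressive edges.
ACTIVE_EDGE_TRUTH <- local({
  tab <- expand.grid(source = c("UP", "NEUTRAL", "DOWN"),
                     target = c("UP", "NEUTRAL", "DOWN"),
                     sign = c(1L, -1L), stringsAsFactors = FALSE)
  key <- paste(tab$source, tab$target, tab$sign)
  tab$active <- key %in% c("UP UP 1", "DOWN DOWN 1",
                           "UP DOWN -1", "DOWN UP -1")
  tab
})

# Independent cascade oracle: brute-force walk enumeration by repeated
# boolean matrix multiplication over the traversable-edge adjacency.
# Edge admissibility is recomputed here from first principles (explicit
# coherence table + first-response scan of the status matrix).
oracle_cascade <- function(network, states, start_tf, temporal = TRUE) {
  genes <- network$nodes$gene
  n <- length(genes)
  fr <- apply(states$status[genes, , drop = FALSE], 1, function(s) {
    i <- which(s != "NEUTRAL")
    if (length(i)) i[1] else NA_integer_
  })
  fs <- vapply(genes, function(g)
    if (is.na(fr[g])) "NEUTRAL" else states$status[g, fr[g]], character(1))
  adj <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  for (k in seq_len(nrow(network$edges))) {
    u <- network$edges$source[k]; v <- network$edges$target[k]
    s <- network$edges$sign[k]
    coh <- ACTIVE_EDGE_TRUTH$active[
      ACTIVE_EDGE_TRUTH$source == fs[u] & ACTIVE_EDGE_TRUTH$target == fs[v] &
        ACTIVE_EDGE_TRUTH$sign == s]
    if (!coh) next
    if (temporal && (is.na(fr[u]) || is.na(fr[v]) || fr[v] < fr[u])) next
    adj[u, v] <- TRUE
  }
  reach <- adj[start_tf, ]
  step <- reach
  for (len in seq_len(n)) {        # walks of every length up to n
    step <- as.logical(step %*% adj)
    names(step) <- genes
    if (!any(step & !reach)) break
    reach <- reach | step
  }
  sort(setdiff(genes[reach], start_tf))
}

# Random trichotomous status matrix (statuses persist once set, like a
# monotone temporal response) for property tests.
random_status_matrix <- function(genes, timepoints, seed,
                                 p = c(0.35, 0.45, 0.2)) {
  withr::with_seed(seed, {
    first <- sample(c(seq_along(timepoints), NA), length(genes),
                    replace = TRUE)
    val <- sample(c("UP", "DOWN"), length(genes), replace = TRUE,
                  prob = c(0.7, 0.3))
    mat <- status_matrix(genes, timepoints)
    for (i in seq_along(genes))
      if (!is.na(first[i]))
        mat[i, seq(first[i], length(timepoints))] <- val[i]
    mat
  })
}
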