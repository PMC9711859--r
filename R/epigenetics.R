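PROMOTER_STATES <- c("ACTIVE_FAIRE", "REPRESSED_K27", "BIVALENT", "UNMARKED")

#' Classify the combinatorial promoter chromatin state of a gene
#'
#' Four-state scheme from promoter log2 enrichments relative to the
#' vehicle control: both H3K4me3 and H3K27me3 above threshold ->
#' `BIVALENT`; H3K27me3 alone above -> `REPRESSED_K27`; H3K4me3 or open
#' chromatin (FAIRE) above, without H3K27me3 -> `ACTIVE_FAIRE`; otherwise
#' `UNMARKED`. RNA polymerase II enrichment is recorded alongside as a
#' descriptive covariate of the transcriptional response and does not
#' enter the classification.
#'
#' @param h3k4,h3k27,faire,rnapii numeric vectors of log2 enrichments
#'   (recycled to a common length); must be finite.
#' @param tau positive enrichment threshold; default 1 (2-fold).
#' @return character vector of states.
#' @examples
#' classify_promoter_state(2, 0.1, 1.5, 1.2, tau = 1)  # ACTIVE_FAIRE
#' classify_promoter_state(0.1, 2, 0, -0.2, tau = 1)   # REPRESSED_K27
#' classify_promoter_state(2, 2, 0.5, 0, tau = 1)      # BIVALENT
#' @export
classify_promoter_state <- function(h3k4, h3k27, faire, rnapii = NULL,
                                    tau = 1) {
  assert_positive(tau, "tau")
  n <- max(length(h3k4), length(h3k27), length(faire))
  h3k4 <- rep_len(h3k4, n); h3k27 <- rep_len(h3k27, n)
  faire <- rep_len(faire, n)
  if (!all(is.finite(h3k4), is.finite(h3k27), is.finite(faire)))
    abort_aegrn("promoter enrichments must be finite", "aegrn_invalid_value")
  k4 <- h3k4 > tau; k27 <- h3k27 > tau; fa <- faire > tau
  state <- rep("UNMARKED", n)
  state[(k4 | fa) & !k27] <- "ACTIVE_FAIRE"
  state[k27 & !k4] <- "REPRESSED_K27"
  state[k27 & k4] <- "BIVALENT"
  state
}

#' Promoter state table from an enrichment data frame
#'
#' @param enrichments data frame with columns `gene`, `h3k4me3`,
#'   `h3k27me3`, `faire`, `rnapii`.
#' @param tau classification threshold, see [classify_promoter_state()].
#' @return a `PromoterStateTable` data frame: the input plus a `state`
#'   column; `tau` is kept as an attribute.
#' @export
promoter_state_table <- function(enrichments, tau = 1) {
  stopifnot(is.data.frame(enrichments),
            all(c("gene", "h3k4me3", "h3k27me3", "faire") %in%
                  names(enrichments)))
  enrichments$state <- classify_promoter_state(
    enrichments$h3k4me3, enrichments$h3k27me3, enrichments$faire,
    enrichments$rnapii, tau = tau)
  attr(enrichments, "tau") <- tau
  class(enrichments) <- c("PromoterStateTable", "data.frame")
  enrichments
}

#' Promoter-state contingency counts over named gene sets
#'
#' @param table a [promoter_state_table()].
#' @param gene_sets named list of gene-id vectors (e.g. program gene
#'   sets). Genes absent from the table are reported via a warning and
#'   skipped.
#' @return integer matrix, one row per gene set, one column per state
#'   (`ACTIVE_FAIRE`, `REPRESSED_K27`, `BIVALENT`, `UNMARKED`).
#' @export
promoter_state_counts <- function(table, gene_sets) {
  stopifnot(inherits(table, "PromoterStateTable"), is.list(gene_sets),
            !is.null(names(gene_sets)))
  missing <- unique(unlist(lapply(gene_sets, setdiff, y = table$gene)))
  if (length(missing))
    warning(sprintf("%d gene(s) absent from promoter table, e.g. %s",
                    length(missing), missing[1]))
  out <- t(vapply(gene_sets, function(gs) {
    st <- table$state[table$gene %in% gs]
    vapply(PROMOTER_STATES, function(s) sum(st == s), integer(1))
  }, integer(length(PROMOTER_STATES))))
  colnames(out) <- PROMOTER_STATES
  out
}
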