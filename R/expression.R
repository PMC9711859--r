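#' Expression matrix with sample metadata
#'
#' Container for normalized gene expression (genes x samples) together with
#' the per-sample design: genotype (cell line), treatment (retinoid ligand
#' or vehicle), timepoint in days, and replicate index. Conditions are
#' addressed throughout as `"genotype:treatment"` labels.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Values must be
#'   non-negative normalized expression.
#' @param sample_meta data frame with columns `sample`, `genotype`,
#'   `treatment`, `timepoint`, `replicate`; one row per column of `values`.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, sample_meta) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)),
            is.data.frame(sample_meta),
            all(c("sample", "genotype", "treatment", "timepoint",
                  "replicate") %in% names(sample_meta)))
  if (anyDuplicated(rownames(values)))
    abort_aegrn("gene ids must be unique", "aegrn_invalid_parameter")
  if (any(values < 0))
    abort_aegrn("expression values must be non-negative",
                "aegrn_invalid_parameter")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ]
  if (any(is.na(sample_meta$sample)))
    abort_aegrn("sample metadata must cover every column of `values`",
                "aegrn_missing_group")
  sample_meta$condition <- paste(sample_meta$genotype, sample_meta$treatment,
                                 sep = ":")
  obj <- list(values = values, samples = sample_meta)
  class(obj) <- "ExpressionMatrix"
  obj
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples, %d conditions, timepoints: %s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$condition)),
              paste(sort(unique(x$samples$timepoint)), collapse = ", ")))
  invisible(x)
}

select_samples <- function(expr, condition, timepoint = NULL) {
  keep <- expr$samples$condition == condition
  if (!is.null(timepoint)) keep <- keep & expr$samples$timepoint == timepoint
  expr$samples$sample[keep]
}

#' Per-gene log2 fold change between two condition groups
#'
#' Replicate samples are aggregated by arithmetic mean on the normalized
#' scale before forming the ratio; a pseudocount guards against zero
#' expression:
#' `log2((mean_case + pseudocount) / (mean_control + pseudocount))`.
#'
#' @param expr an [expression_matrix()].
#' @param case_group,control_group condition labels `"genotype:treatment"`.
#' @param timepoint timepoint (in days) at which both groups are compared;
#'   `NULL` pools all timepoints of each group.
#' @param pseudocount non-negative value added to both means; default 1.
#' @return named numeric vector of log2 fold changes, one per gene.
#' @examples
#' expr <- expression_matrix(
#'   matrix(c(8, 1), 1, 2, dimnames = list("G1", c("s1", "s2"))),
#'   data.frame(sample = c("s1", "s2"), genotype = "WT",
#'              treatment = c("ATRA", "EtOH"), timepoint = 2, replicate = 1))
#' compute_log2fc(expr, "WT:ATRA", "WT:EtOH", timepoint = 2, pseudocount = 0)
#' @export
compute_log2fc <- function(expr, case_group, control_group, timepoint = NULL,
                           pseudocount = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!is.numeric(pseudocount) || pseudocount < 0)
    abort_aegrn("`pseudocount` must be non-negative", "aegrn_invalid_parameter")
  case_s <- select_samples(expr, case_group, timepoint)
  ctrl_s <- select_samples(expr, control_group, timepoint)
  if (length(case_s) == 0L)
    abort_aegrn(sprintf("no samples for case group '%s'%s", case_group,
                        if (is.null(timepoint)) "" else
                          sprintf(" at timepoint %s", timepoint)),
                "aegrn_missing_group")
  if (length(ctrl_s) == 0L)
    abort_aegrn(sprintf("no samples for control group '%s'", control_group),
                "aegrn_missing_group")
  mean_case <- rowMeans(expr$values[, case_s, drop = FALSE])
  mean_ctrl <- rowMeans(expr$values[, ctrl_s, drop = FALSE])
  if (pseudocount == 0 && any(mean_ctrl == 0))
    abort_aegrn("zero control mean with pseudocount 0: ratio undefined",
                "aegrn_undefined_ratio")
  log2((mean_case + pseudocount) / (mean_ctrl + pseudocount))
}

#' Trichotomous differential-expression call from log2 fold changes
#'
#' Strict thresholding: `UP` iff log2fc > `threshold_log2`, `DOWN` iff
#' log2fc < -`threshold_log2`, otherwise `NEUTRAL`. A value exactly equal
#' to the threshold is `NEUTRAL`.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param threshold_log2 positive log2 threshold (2 corresponds to a
#'   4-fold change, the default used for endpoint DEG analyses; 1 for the
#'   more permissive path stratification).
#' @return character vector of statuses in `{"UP", "DOWN", "NEUTRAL"}`.
#' @export
call_de_status <- function(log2fc, threshold_log2 = 2) {
  assert_positive(threshold_log2, "threshold_log2")
  status <- rep("NEUTRAL", length(log2fc))
  status[log2fc > threshold_log2] <- "UP"
  status[log2fc < -threshold_log2] <- "DOWN"
  names(status) <- names(log2fc)
  status
}

#' Differential-expression status table across conditions and timepoints
#'
#' Computes per-gene log2 fold changes of every non-control condition
#' against the control treatment at the matched timepoint, and calls
#' trichotomous status at a fold-change threshold.
#'
#' @param expr an [expression_matrix()].
#' @param control control condition label `"genotype:treatment"` (the
#'   vehicle sample), or a bare treatment label matched within each
#'   genotype.
#' @param threshold_log2 positive log2 fold-change threshold; default 2.
#' @param pseudocount pseudocount for [compute_log2fc()]; default 1.
#' @param conditions optional subset of condition labels to evaluate;
#'   default all non-control conditions.
#' @param timepoints optional subset of timepoints; default all.
#' @return a `DEStatusTable`: a data frame with columns `gene`,
#'   `condition`, `timepoint`, `log2fc`, `status`, with the threshold in
#'   attribute `threshold_log2`.
#' @export
de_status_table <- function(expr, control, threshold_log2 = 2,
                            pseudocount = 1, conditions = NULL,
                            timepoints = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  assert_positive(threshold_log2, "threshold_log2")
  meta <- expr$samples
  is_ctrl_cond <- if (grepl(":", control, fixed = TRUE)) {
    meta$condition == control
  } else meta$treatment == control
  if (!any(is_ctrl_cond))
    abort_aegrn(sprintf("control '%s' not found in sample metadata", control),
                "aegrn_missing_group")
  conditions <- conditions %||% setdiff(unique(meta$condition),
                                        unique(meta$condition[is_ctrl_cond]))
  timepoints <- timepoints %||% sort(unique(meta$timepoint))
  rows <- list()
  for (cond in conditions) {
    geno <- sub(":.*$", "", cond)
    ctrl_cond <- if (grepl(":", control, fixed = TRUE)) control else
      paste(geno, control, sep = ":")
    if (!any(meta$condition == ctrl_cond))
      ctrl_cond <- unique(meta$condition[is_ctrl_cond])[1]
    for (tp in timepoints) {
      if (!any(meta$condition == cond & meta$timepoint == tp)) next
      lfc <- compute_log2fc(expr, cond, ctrl_cond, timepoint = tp,
                            pseudocount = pseudocount)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = names(lfc), condition = cond, timepoint = tp,
        log2fc = unname(lfc),
        status = call_de_status(lfc, threshold_log2),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "threshold_log2") <- threshold_log2
  class(tab) <- c("DEStatusTable", "data.frame")
  tab
}

#' Count differentially expressed genes
#'
#' @param status_table a [de_status_table()].
#' @param condition condition label present in the table.
#' @param direction `"UP"`, `"DOWN"` or `"ANY"` (any non-NEUTRAL status).
#' @param timepoint optional timepoint filter.
#' @return integer count of genes with the requested status.
#' @export
count_degs <- function(status_table, condition, direction = c("ANY", "UP", "DOWN"),
                       timepoint = NULL) {
  direction <- match.arg(direction)
  keep <- status_table$condition == condition
  if (!any(keep))
    abort_aegrn(sprintf("condition '%s' not present in status table", condition),
                "aegrn_missing_group")
  if (!is.null(timepoint)) keep <- keep & status_table$timepoint == timepoint
  st <- status_table$status[keep]
  sum(if (direction == "ANY") st != "NEUTRAL" else st == direction)
}
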