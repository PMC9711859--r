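# Readers and writers for the pipeline's plain-text formats. TSV is the
# canonical tabular dialect: tab-delimited, header row, UTF-8, '.'
# decimal; gzip-compressed files are read transparently.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path))
    abort_aegrn(sprintf("%s file not found: %s", what, path),
                "aegrn_missing_file")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    abort_aegrn(sprintf("%s file %s lacks column(s): %s", what, path,
                        paste(miss, collapse = ", ")),
                "aegrn_parse_error")
  tab
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix with sample metadata
#'
#' The expression TSV has genes in rows (first column `gene`) and one
#' column per sample; the metadata TSV has columns `sample`, `genotype`,
#' `treatment`, `timepoint`, `replicate`.
#'
#' @param values_path,meta_path file paths.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(values_path, meta_path) {
  vals <- read_tsv_checked(values_path, "gene", "expression")
  meta <- read_tsv_checked(meta_path, c("sample", "genotype", "treatment",
                                        "timepoint", "replicate"),
                           "sample metadata")
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$gene
  expression_matrix(m, meta)
}

#' @rdname read_expression_tsv
#' @param expr an `ExpressionMatrix`.
#' @export
write_expression_tsv <- function(expr, values_path, meta_path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  write_tsv(data.frame(gene = rownames(expr$values), expr$values,
                       check.names = FALSE), values_path)
  meta <- expr$samples
  meta$condition <- NULL
  write_tsv(meta, meta_path)
  invisible(c(values_path, meta_path))
}

#' Read / write a signed edge list (TSV or SIF dialect)
#'
#' The TSV dialect has columns `source`, `target`, `sign` (+1/-1). The
#' SIF dialect is `source<TAB>interaction<TAB>target` with interaction
#' `activates` or `represses`; malformed rows are reported with their
#' line number.
#'
#' @param path file path.
#' @param tfs optional TF node ids (default: all observed sources).
#' @return a `RegulatoryNetwork`.
#' @export
read_edge_tsv <- function(path, tfs = NULL) {
  tab <- read_tsv_checked(path, c("source", "target", "sign"), "edge list")
  bad <- which(!tab$sign %in% c(-1, 1))
  if (length(bad))
    abort_aegrn(sprintf("edge list %s line %d: sign must be +1 or -1 (got '%s')",
                        path, bad[1] + 1L, tab$sign[bad[1]]),
                "aegrn_parse_error")
  regulatory_network(tab, tfs = tfs)
}

#' @rdname read_edge_tsv
#' @param network a `RegulatoryNetwork`.
#' @export
write_edge_tsv <- function(network, path) {
  stopifnot(inherits(network, "RegulatoryNetwork"))
  write_tsv(network$edges[, c("source", "target", "sign")], path)
}

#' @rdname read_edge_tsv
#' @export
read_sif <- function(path, tfs = NULL) {
  if (!file.exists(path))
    abort_aegrn(sprintf("SIF file not found: %s", path), "aegrn_missing_file")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_f <- lengths(parts)
  if (any(n_f != 3L))
    abort_aegrn(sprintf("SIF %s line %d: expected 3 tab-separated fields, got %d",
                        path, which(n_f != 3L)[1], n_f[n_f != 3L][1]),
                "aegrn_parse_error")
  inter <- vapply(parts, `[`, character(1), 2L)
  bad <- which(!inter %in% c("activates", "represses"))
  if (length(bad))
    abort_aegrn(sprintf("SIF %s line %d: unknown interaction '%s' (expected activates/represses)",
                        path, bad[1], inter[bad[1]]),
                "aegrn_parse_error")
  regulatory_network(data.frame(
    source = vapply(parts, `[`, character(1), 1L),
    target = vapply(parts, `[`, character(1), 3L),
    sign = ifelse(inter == "activates", 1L, -1L),
    stringsAsFactors = FALSE), tfs = tfs)
}

#' @rdname read_edge_tsv
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "RegulatoryNetwork"))
  writeLines(paste(network$edges$source,
                   ifelse(network$edges$sign > 0, "activates", "represses"),
                   network$edges$target, sep = "\t"), path)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#'
#' @param path file path.
#' @return named list of character vectors (set name -> members), with
#'   descriptions in attribute `description`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    abort_aegrn(sprintf("GMT file not found: %s", path), "aegrn_missing_file")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    abort_aegrn(sprintf("GMT %s line %d: fewer than 3 fields", path, short[1]),
                "aegrn_parse_error")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% attr(sets, "description") %||%
    rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Write a marker catalog as GMT (classes and subtypes)
#' @param catalog a [marker_catalog()].
#' @param path file path.
#' @export
write_marker_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "MarkerCatalog"))
  sets <- c(catalog$class_sets, catalog$subtype_sets)
  write_gmt(sets, path,
            descriptions = c(rep("class", length(catalog$class_sets)),
                             rep("subtype", length(catalog$subtype_sets))))
}

#' Build a marker catalog from a GMT file
#'
#' Set names listed in `subtype_labels` become neuron subtypes; the rest
#' are top-level classes, in file order.
#'
#' @param path GMT file path.
#' @param subtype_labels names of the neuron-subtype sets; default the
#'   canonical dopaminergic/glutamatergic/GABAergic trio.
#' @param neuron_class the class carrying subtypes; default `"neuron"`.
#' @return a [marker_catalog()].
#' @export
read_marker_gmt <- function(path,
                            subtype_labels = c("dopaminergic",
                                               "glutamatergic", "GABAergic"),
                            neuron_class = "neuron") {
  sets <- read_gmt(path)
  is_sub <- names(sets) %in% subtype_labels
  marker_catalog(sets[!is_sub], sets[is_sub], neuron_class = neuron_class)
}

#' Read / write promoter enrichment tables
#' @param path file path.
#' @return data frame with columns `gene`, `h3k4me3`, `h3k27me3`,
#'   `faire`, `rnapii`.
#' @export
read_promoter_tsv <- function(path) {
  read_tsv_checked(path, c("gene", "h3k4me3", "h3k27me3", "faire"),
                   "promoter enrichment")
}

#' @rdname read_promoter_tsv
#' @param table promoter enrichment data frame.
#' @export
write_promoter_tsv <- function(table, path) write_tsv(table, path)

#' Read a BED file of promoter intervals
#'
#' Coordinates follow the BED standard: 0-based, half-open, so interval
#' length is `end - start`.
#'
#' @param path BED file path (>= 3 columns: chrom, start, end; optional
#'   name, score, strand).
#' @return data frame with columns `chrom`, `start`, `end`, `width` and,
#'   when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path))
    abort_aegrn(sprintf("BED file not found: %s", path), "aegrn_missing_file")
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    abort_aegrn(sprintf("BED %s: expected >= 3 columns", path),
                "aegrn_parse_error")
  names(tab)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  if (ncol(tab) > 3L)
    names(tab)[4:min(6L, ncol(tab))] <- extra[seq_len(min(3L, ncol(tab) - 3L))]
  bad <- which(tab$start < 0 | tab$end <= tab$start)
  if (length(bad))
    abort_aegrn(sprintf("BED %s line %d: invalid interval [%s, %s)",
                        path, bad[1], tab$start[bad[1]], tab$end[bad[1]]),
                "aegrn_parse_error")
  tab$width <- tab$end - tab$start
  tab
}

#' Write a DE status table as TSV
#' @param status_table a [de_status_table()].
#' @param path file path.
#' @export
write_de_tsv <- function(status_table, path) {
  write_tsv(as.data.frame(status_table), path)
}

#' Write an active-edge set as TSV
#' @param active an `ActiveEdgeSet`.
#' @param network the network it was evaluated on.
#' @param path file path.
#' @export
write_active_edges_tsv <- function(active, network, path) {
  stopifnot(inherits(active, "ActiveEdgeSet"))
  ed <- network$edges[network$edges$edge_id %in% active$edge_ids, ]
  ed$condition <- active$condition
  ed$timepoint <- active$timepoint
  write_tsv(ed, path)
}

#' Write the synthetic ground truth as JSON
#' @param truth a [synthetic_truth()].
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  payload <- list(
    planted_masters = truth$planted_masters,
    planted_program_edges = truth$planted_program_edges,
    inhibited_edge_set = truth$inhibited_edge_set,
    silenced_genes = truth$silenced_genes,
    path_membership = as.list(truth$path_membership),
    noise_sd = truth$noise_sd, timepoints = truth$timepoints,
    seed = truth$seed)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                              digits = 10), path)
  invisible(path)
}
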