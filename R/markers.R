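#' Hierarchical cell-type marker catalog
#'
#' Two-level catalog of marker gene sets: top-level specialized-cell
#' classes (canonically neuron, astrocyte and oligodendrocyte precursor,
#' OPC) and neuron subtypes (canonically dopaminergic, glutamatergic,
#' GABAergic). Marker sources overlap, so annotation resolves multiple
#' memberships by a first-match priority order over labels. Gene ids are
#' matched case-insensitively after whitespace stripping.
#'
#' @param class_sets named list of character vectors: top-level class
#'   label -> marker gene ids.
#' @param subtype_sets named list of character vectors: neuron-subtype
#'   label -> marker gene ids. Subtype labels are only interpreted for
#'   genes that received the neuron class.
#' @param class_priority order in which class labels are tried; default
#'   the order of `class_sets`.
#' @param subtype_priority order for subtype labels; default the order of
#'   `subtype_sets`.
#' @param neuron_class the class label whose members are eligible for
#'   subtype annotation; default the first class label.
#' @return an object of class `MarkerCatalog`.
#' @export
marker_catalog <- function(class_sets, subtype_sets = list(),
                           class_priority = names(class_sets),
                           subtype_priority = names(subtype_sets),
                           neuron_class = names(class_sets)[1]) {
  if (length(class_sets) == 0L || is.null(names(class_sets)) ||
      any(names(class_sets) == ""))
    abort_aegrn("class_sets must be a non-empty named list",
                "aegrn_invalid_catalog")
  if (anyDuplicated(c(names(class_sets), names(subtype_sets))))
    abort_aegrn("marker labels must be unique", "aegrn_invalid_catalog")
  if (!setequal(class_priority, names(class_sets)))
    abort_aegrn("class_priority must cover exactly the class labels",
                "aegrn_invalid_catalog")
  norm <- function(sets) lapply(sets, normalize_gene_id)
  obj <- list(class_sets = norm(class_sets),
              subtype_sets = norm(subtype_sets),
              class_priority = class_priority,
              subtype_priority = subtype_priority,
              neuron_class = neuron_class)
  class(obj) <- "MarkerCatalog"
  obj
}

#' @export
print.MarkerCatalog <- function(x, ...) {
  cat("MarkerCatalog\n  classes: ",
      paste(sprintf("%s (%d)", x$class_priority,
                    lengths(x$class_sets)[x$class_priority]), collapse = ", "),
      "\n", sep = "")
  if (length(x$subtype_sets))
    cat("  ", x$neuron_class, " subtypes: ",
        paste(sprintf("%s (%d)", x$subtype_priority,
                      lengths(x$subtype_sets)[x$subtype_priority]),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Annotate genes with cell-type class and neuron subtype
#'
#' Each gene receives exactly one class: the first label in priority order
#' whose marker set contains it, else `"UNASSIGNED"`. Genes carrying the
#' neuron class additionally receive exactly one subtype by subtype
#' priority, else `"UNASSIGNED"`; subtype membership of non-neuron genes
#' is ignored.
#'
#' @param genes character vector of gene ids.
#' @param catalog a [marker_catalog()].
#' @return data frame with columns `gene`, `class`, `subtype`.
#' @examples
#' cat <- marker_catalog(list(neuron = "g1", astrocyte = c("g1", "g2")),
#'                       list(GABAergic = "g1"))
#' annotate_genes(c("g1", "g2", "g3"), cat)
#' @export
annotate_genes <- function(genes, catalog) {
  stopifnot(inherits(catalog, "MarkerCatalog"))
  key <- normalize_gene_id(genes)
  cls <- rep("UNASSIGNED", length(genes))
  for (lab in rev(catalog$class_priority))
    cls[key %in% catalog$class_sets[[lab]]] <- lab
  sub <- rep("UNASSIGNED", length(genes))
  for (lab in rev(catalog$subtype_priority))
    sub[key %in% catalog$subtype_sets[[lab]]] <- lab
  sub[cls != catalog$neuron_class] <- "UNASSIGNED"
  data.frame(gene = genes, class = cls, subtype = sub,
             stringsAsFactors = FALSE)
}

#' Marker composition of each co-expression path
#'
#' Counts annotated member genes per path, per top-level class and per
#' neuron subtype.
#'
#' @param assignment a [assign_paths()] result.
#' @param catalog a [marker_catalog()].
#' @return data frame with one row per non-empty path: `path_id`,
#'   `signature`, `n`, one count column per class label (plus
#'   `class_UNASSIGNED`) and one per subtype label.
#' @export
marker_counts_per_path <- function(assignment, catalog) {
  stopifnot(inherits(assignment, "PathAssignment"),
            inherits(catalog, "MarkerCatalog"))
  ann <- annotate_genes(assignment$assignment$gene, catalog)
  ann$path_id <- assignment$assignment$path_id
  sizes <- assignment$sizes[assignment$sizes$n > 0 &
                              !is.na(assignment$sizes$path_id), ]
  out <- sizes[, c("path_id", "signature", "n")]
  for (lab in c(catalog$class_priority, "UNASSIGNED")) {
    cnt <- vapply(out$path_id, function(p)
      sum(ann$class == lab & !is.na(ann$path_id) & ann$path_id == p),
      integer(1))
    out[[if (lab == "UNASSIGNED") "class_UNASSIGNED" else lab]] <- cnt
  }
  for (lab in catalog$subtype_priority)
    out[[lab]] <- vapply(out$path_id, function(p)
      sum(ann$subtype == lab & !is.na(ann$path_id) & ann$path_id == p),
      integer(1))
  rownames(out) <- NULL
  out
}

#' Marker recovery relative to a gold-standard condition
#'
#' For each marker label L, the fraction of gold-standard up-regulated
#' marker genes that the test condition also up-regulates:
#' `|test_up ∩ gold_up ∩ L| / |gold_up ∩ L|`, reported in percent. The raw
#' value may exceed 100 when capping for display is not applied here;
#' labels whose gold intersection is empty are undefined and reported as
#' `NA`, never as zero.
#'
#' @param test_up character vector: up-regulated genes in the test
#'   condition.
#' @param gold_up character vector: up-regulated genes in the
#'   gold-standard condition.
#' @param catalog a [marker_catalog()].
#' @return named numeric vector of percentages over all class and subtype
#'   labels.
#' @export
gold_standard_fraction <- function(test_up, gold_up, catalog) {
  stopifnot(inherits(catalog, "MarkerCatalog"))
  test_up <- normalize_gene_id(test_up)
  gold_up <- normalize_gene_id(gold_up)
  sets <- c(catalog$class_sets, catalog$subtype_sets)
  vapply(sets, function(markers) {
    gold_m <- intersect(gold_up, markers)
    if (length(gold_m) == 0L) return(NA_real_)
    100 * length(intersect(test_up, gold_m)) / length(gold_m)
  }, numeric(1))
}
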