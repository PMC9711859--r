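#' Canonical co-expression path signature table
#'
#' A co-expression path is the ordered trichotomous status signature of a
#' gene across timepoints, e.g. `(UP, UP, UP)` for genes up-regulated early
#' and persistently. The full `3^T` signature space is enumerated; path ids
#' are assigned deterministically in lexicographic order with
#' `UP < NEUTRAL < DOWN` and the earliest timepoint most significant. For
#' the canonical three-timepoint design, three ids are pinned to the
#' named paths of the field: Path 1 = `(UP, UP, UP)` (early and sustained
#' induction), Path 2 = `(NEUTRAL, UP, UP)` (induced from the middle
#' timepoint) and Path 4 = `(NEUTRAL, NEUTRAL, UP)` (late induction); all
#' other signatures take the remaining ids in lexicographic order. The
#' all-`NEUTRAL` signature carries no path id (`NA`): it is not a
#' differential-response path.
#'
#' @param n_timepoints number of timepoints (>= 1).
#' @return data frame with columns `signature` (statuses joined by `"/"`)
#'   and `path_id` (integer, `NA` for the all-NEUTRAL signature).
#' @examples
#' head(path_signature_table(3))
#' @export
path_signature_table <- function(n_timepoints = 3) {
  n_timepoints <- assert_count(n_timepoints, "n_timepoints", min = 1L)
  lv <- STATUS_LEVELS  # UP < NEUTRAL < DOWN
  grid <- do.call(expand.grid,
                  c(rep(list(lv), n_timepoints),
                    list(stringsAsFactors = FALSE)))
  # expand.grid varies the first column fastest; the earliest timepoint
  # must be most significant, so it maps to the last grid column.
  sig <- apply(grid[, rev(seq_len(n_timepoints)), drop = FALSE], 1,
               paste, collapse = "/")
  all_neutral <- paste(rep("NEUTRAL", n_timepoints), collapse = "/")
  path_id <- rep(NA_integer_, length(sig))
  pinned <- if (n_timepoints == 3) c(
    "UP/UP/UP" = 1L, "NEUTRAL/UP/UP" = 2L, "NEUTRAL/NEUTRAL/UP" = 4L
  ) else integer()
  path_id[match(names(pinned), sig)] <- pinned
  free <- is.na(path_id) & sig != all_neutral
  path_id[free] <- setdiff(seq_len(length(sig) - 1L), pinned)[seq_len(sum(free))]
  data.frame(signature = sig, path_id = path_id, stringsAsFactors = FALSE)
}

#' Assign genes to temporal co-expression paths
#'
#' Maps each gene's per-timepoint DE status under one condition to its
#' signature and canonical path id (see [path_signature_table()]).
#'
#' @param status_table a [de_status_table()] holding statuses for every
#'   listed timepoint of `condition`.
#' @param condition condition label `"genotype:treatment"`.
#' @param timepoints ordered vector of timepoints defining the signature.
#' @return a `PathAssignment`: list with `assignment` (data frame `gene`,
#'   `signature`, `path_id`), `sizes` (data frame `path_id`, `signature`,
#'   `n`, `relevant`, descending by membership), plus `condition` and
#'   `timepoints`. Genes with the all-NEUTRAL signature have `path_id` NA
#'   and are never relevant.
#' @export
assign_paths <- function(status_table, condition, timepoints) {
  stopifnot(inherits(status_table, "data.frame"),
            length(timepoints) >= 1L)
  sub <- status_table[status_table$condition == condition &
                        status_table$timepoint %in% timepoints, ]
  if (nrow(sub) == 0L)
    abort_aegrn(sprintf("condition '%s' not present in status table", condition),
                "aegrn_missing_group")
  genes <- sort(unique(sub$gene))
  mat <- matrix(NA_character_, length(genes), length(timepoints),
                dimnames = list(genes, as.character(timepoints)))
  idx <- cbind(match(sub$gene, genes), match(sub$timepoint, timepoints))
  mat[idx] <- sub$status
  if (anyNA(mat))
    abort_aegrn("incomplete status series: some gene lacks a status at a listed timepoint",
                "aegrn_incomplete_series")
  sig <- apply(mat, 1, paste, collapse = "/")
  sig_tab <- path_signature_table(length(timepoints))
  assignment <- data.frame(
    gene = genes, signature = unname(sig),
    path_id = sig_tab$path_id[match(sig, sig_tab$signature)],
    stringsAsFactors = FALSE)
  counts <- table(factor(assignment$signature, levels = sig_tab$signature))
  sizes <- data.frame(path_id = sig_tab$path_id,
                      signature = sig_tab$signature,
                      n = as.integer(counts), stringsAsFactors = FALSE)
  sizes$relevant <- sizes$n > 0L & !is.na(sizes$path_id)
  sizes <- sizes[order(-sizes$n, sizes$path_id), ]
  rownames(sizes) <- NULL
  out <- list(assignment = assignment, sizes = sizes,
              condition = condition, timepoints = timepoints)
  class(out) <- "PathAssignment"
  out
}

#' @export
print.PathAssignment <- function(x, ...) {
  cat(sprintf("PathAssignment (%s; timepoints %s): %d genes, %d non-empty paths\n",
              x$condition, paste(x$timepoints, collapse = ", "),
              nrow(x$assignment), sum(x$sizes$n > 0 & !is.na(x$sizes$path_id))))
  print(utils::head(x$sizes[x$sizes$n > 0, ], 10))
  invisible(x)
}

#' Filter paths by minimum membership
#'
#' Marks paths with fewer than `min_members` genes as not relevant,
#' reproducing the study convention of reporting only well-populated
#' co-expression paths.
#'
#' @param assignment a [assign_paths()] result.
#' @param min_members minimum number of member genes; default 1.
#' @return the `PathAssignment` with updated `relevant` flags; ordering of
#'   `sizes` (descending membership) is stable.
#' @export
relevant_paths <- function(assignment, min_members = 1) {
  stopifnot(inherits(assignment, "PathAssignment"))
  min_members <- assert_count(min_members, "min_members")
  assignment$sizes$relevant <- assignment$sizes$n >= min_members &
    assignment$sizes$n > 0L & !is.na(assignment$sizes$path_id)
  assignment
}

#' Member genes of one path
#' @param assignment a `PathAssignment`.
#' @param path_id integer path id.
#' @return character vector of gene ids.
#' @export
path_members <- function(assignment, path_id) {
  stopifnot(inherits(assignment, "PathAssignment"))
  assignment$assignment$gene[!is.na(assignment$assignment$path_id) &
                               assignment$assignment$path_id == path_id]
}

#' Does a path signature contain an up-regulated timepoint?
#'
#' Predicate selecting paths up-regulated at least at one timepoint (the
#' criterion used to pick paths for downstream functional analysis).
#'
#' @param signature character vector of `"/"`-joined signatures.
#' @return logical vector.
#' @export
contains_up <- function(signature) {
  vapply(strsplit(signature, "/", fixed = TRUE),
         function(s) any(s == "UP"), logical(1))
}
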