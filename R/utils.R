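# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage-specific sub-seed from a master seed
#'
#' All randomness in the package flows from one user-supplied seed; each
#' stochastic stage draws from a distinct stream obtained by mixing the
#' master seed with a small stage offset. Results stay within 32-bit
#' integer range.
#'
#' @param seed master integer seed.
#' @param offset small non-negative integer identifying the stage.
#' @return an integer seed.
#' @keywords internal
sub_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}

abort_aegrn <- function(msg, class) {
  stop(structure(
    class = c(class, "aegrn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort_aegrn(sprintf("`%s` must be a single value in [0, 1], got %s",
                        name, paste(format(x), collapse = ", ")),
                "aegrn_invalid_parameter")
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    abort_aegrn(sprintf("`%s` must be a single integer >= %d", name, min),
                "aegrn_invalid_parameter")
  invisible(as.integer(x))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    abort_aegrn(sprintf("`%s` must be a single positive number", name),
                "aegrn_invalid_parameter")
  invisible(x)
}

# Canonical trichotomous status levels used throughout.
STATUS_LEVELS <- c("UP", "NEUTRAL", "DOWN")

status_to_sign <- function(status) {
  s <- integer(length(status))
  s[status == "UP"] <- 1L
  s[status == "DOWN"] <- -1L
  s
}

normalize_gene_id <- function(x) toupper(trimws(x))
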