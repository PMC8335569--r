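# internal helpers shared across modules

#' Truncate sample barcodes to a common prefix
#'
#' TCGA-style barcodes carry assay-specific suffixes; truncating both the
#' mutation and expression identifiers to the sample-level prefix (first 15
#' characters for TCGA) makes them comparable across assays.
#'
#' @param x character vector of sample identifiers.
#' @param n prefix length to keep; `NULL` leaves identifiers untouched.
#' @return character vector of truncated identifiers.
#' @export
truncate_barcode <- function(x, n = 15L) {
  if (is.null(n)) return(x)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1L)
  substr(as.character(x), 1L, as.integer(n))
}

.assert_matrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(sprintf("%s must have row and column names", what), call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop(sprintf("%s has duplicated row names", what), call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop(sprintf("%s has duplicated column names", what), call. = FALSE)
  invisible(m)
}

.assert_binary <- function(m, what) {
  .assert_matrix(m, what)
  if (!all(m %in% c(0, 1)))
    stop(sprintf("%s must contain only 0/1", what), call. = FALSE)
  invisible(m)
}

# deterministic per-item seed derivation, kept below 2^31
.derive_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}
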