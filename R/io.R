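# Readers and writers for the external formats the pipeline touches:
# MAF somatic variant calls, GMT gene-set collections, genes x samples
# expression / cells x samples abundance TSV matrices, and survival tables.
# All text I/O is UTF-8 with '.' as the decimal separator.

.maf_required <- c("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode")

#' Read somatic variant calls from a MAF file
#'
#' Parses a tab-separated mutation annotation format (MAF, GDC dialect) file.
#' Lines starting with `#` are treated as comments. Columns are located by
#' header name (after whitespace trimming), so column order is irrelevant; at
#' least `Hugo_Symbol`, `Variant_Classification` and `Tumor_Sample_Barcode`
#' must be present.
#'
#' @param path path to a MAF file.
#' @return a data frame with one row per variant record, in file order, with
#'   columns `gene_symbol`, `variant_classification`, `sample_barcode`.
#' @seealso [build_mutation_matrix()]
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("MAF file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(df) <- trimws(names(df))
  missing <- setdiff(.maf_required, names(df))
  if (length(missing))
    stop("MAF is missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    gene_symbol = trimws(df[["Hugo_Symbol"]]),
    variant_classification = trimws(df[["Variant_Classification"]]),
    sample_barcode = trimws(df[["Tumor_Sample_Barcode"]]),
    stringsAsFactors = FALSE
  )
  if (nrow(out) && any(!nzchar(out$gene_symbol) |
                       !nzchar(out$variant_classification) |
                       !nzchar(out$sample_barcode)))
    stop("MAF contains records with empty gene, classification or barcode fields",
         call. = FALSE)
  out
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects gene identifiers in the first column and sample identifiers in the
#' header row. Duplicate gene rows are collapsed by keeping the row with the
#' highest mean expression. Any non-numeric body cell (including `NA`) is a
#' format error.
#'
#' @param path path to a tab-separated matrix file.
#' @return numeric matrix with gene row names and sample column names.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged TSV: line %d has %d fields, expected %d",
                 bad, nf[bad], nf[1L]), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 3L) stop("expression matrix needs >= 2 sample columns", call. = FALSE)
  ids <- trimws(df[[1L]])
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(vals <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 body[bad[1L], bad[2L]], ids[bad[1L]],
                 colnames(df)[-1L][bad[2L]]), call. = FALSE)
  }
  dimnames(vals) <- list(ids, trimws(colnames(df)[-1L]))
  if (anyDuplicated(colnames(vals)))
    stop("duplicated sample identifiers in header", call. = FALSE)
  if (!all(is.finite(vals))) stop("non-finite values in matrix body", call. = FALSE)
  if (anyDuplicated(ids)) {
    # keep the max-mean row per duplicated gene id (deterministic)
    means <- rowMeans(vals)
    ord <- order(ids, -means)
    keep <- ord[!duplicated(ids[ord])]
    vals <- vals[sort(keep), , drop = FALSE]
  }
  vals
}

#' Write a labelled numeric matrix to TSV
#'
#' The inverse of [read_expression()]: values are serialized with 17
#' significant digits so that a write/read cycle reproduces the matrix
#' bit-identically.
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @param id_label header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_label = "id") {
  .assert_matrix(m, "matrix")
  chr <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  lines <- c(
    paste(c(id_label, colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)),
           function(i) paste(c(rownames(m)[i], chr[i, ]), collapse = "\t"),
           character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line is `name TAB description TAB gene1 TAB gene2 ...`. Set names must
#' be unique and every set non-empty; within-set duplicate genes are dropped.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, genes",
                   i, length(f)), call. = FALSE)
    genes <- unique(trimws(f[-c(1L, 2L)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("GMT set '%s' (line %d) has no genes", f[1L], i), call. = FALSE)
    stats::setNames(list(genes), trimws(f[1L]))
  })
  out <- unlist(sets, recursive = FALSE)
  if (anyDuplicated(names(out)))
    stop("duplicated gene-set names in GMT", call. = FALSE)
  out
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a survival table
#'
#' Tab-separated table with one row per sample: a sample identifier, a
#' positive follow-up time (units are the caller's concern) and a 0/1 event
#' indicator (1 = death/event observed, 0 = censored).
#'
#' @param path path to the TSV file.
#' @param sample_col,time_col,event_col column names holding the identifier,
#'   time and event status.
#' @return data frame with columns `sample`, `time`, `event`.
#' @export
read_survival <- function(path, sample_col = "sample", time_col = "time",
                          event_col = "event") {
  if (!file.exists(path)) stop("survival file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  for (col in c(sample_col, time_col, event_col))
    if (!col %in% names(df))
      stop("survival table is missing column: ", col, call. = FALSE)
  out <- data.frame(sample = as.character(df[[sample_col]]),
                    time = as.numeric(df[[time_col]]),
                    event = as.numeric(df[[event_col]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample))
    stop("duplicated sample identifiers in survival table", call. = FALSE)
  if (anyNA(out$time) || any(out$time <= 0))
    stop("survival times must be positive", call. = FALSE)
  if (!all(out$event %in% c(0, 1)))
    stop("event indicator must be 0 or 1", call. = FALSE)
  out
}

#' Write a survival table to TSV
#'
#' @param surv data frame as returned by [read_survival()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(surv, path) {
  stopifnot(all(c("sample", "time", "event") %in% names(surv)))
  utils::write.table(surv[, c("sample", "time", "event")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a precomputed cell abundance matrix
#'
#' Reads a cells-by-samples TSV produced by an external deconvolution tool
#' (for example xCell or CIBERSORT scores), truncates its sample barcodes,
#' and aligns columns to an expected sample set. Extra samples are dropped
#' with a warning; missing expected samples are an error.
#'
#' @param path path to the TSV matrix.
#' @param expected_samples character vector of sample identifiers that must
#'   all be present (after barcode truncation).
#' @param barcode_length prefix length used to reconcile barcodes; `NULL`
#'   disables truncation.
#' @return numeric cells-by-samples matrix with columns in
#'   `expected_samples` order.
#' @export
import_abundance <- function(path, expected_samples, barcode_length = NULL) {
  m <- read_expression(path)
  colnames(m) <- truncate_barcode(colnames(m), barcode_length)
  if (anyDuplicated(colnames(m)))
    stop("barcode truncation produced duplicate sample identifiers", call. = FALSE)
  expected <- truncate_barcode(expected_samples, barcode_length)
  missing <- setdiff(expected, colnames(m))
  if (length(missing))
    stop("abundance matrix is missing expected sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(colnames(m), expected)
  if (length(extra))
    warning(length(extra), " extra sample column(s) dropped", call. = FALSE)
  m[, expected, drop = FALSE]
}
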