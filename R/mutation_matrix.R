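# MAF records -> binary gene x sample mutation matrix with non-silent
# filtering and mutation-frequency thresholding.

# canonical MAF Variant_Classification tokens for protein-altering variants
.nonsilent_tokens <- c(
  "Nonsense_Mutation", "Missense_Mutation", "Frame_Shift_Del",
  "Frame_Shift_Ins", "Splice_Site", "Nonstop_Mutation",
  "Translation_Start_Site", "In_Frame_Del", "In_Frame_Ins"
)

#' Is a MAF variant classification non-silent?
#'
#' Non-silent (protein-altering) classes are nonsense, missense, frameshift
#' indels, splice site, nonstop, translation start site and in-frame indels.
#' Comparison against the canonical MAF tokens is case-insensitive; unknown
#' tokens are silent.
#'
#' @param variant_classification character vector of MAF
#'   `Variant_Classification` tokens.
#' @return logical vector.
#' @export
classify_nonsilent <- function(variant_classification) {
  tolower(as.character(variant_classification)) %in% tolower(.nonsilent_tokens)
}

#' Build the binary mutation matrix from MAF records
#'
#' Cell (g, s) is 1 when sample s carries at least one non-silent variant of
#' gene g, else 0. Samples in the declared universe with no records get
#' all-zero columns; the per-gene mutation frequency is the row sum divided
#' by the universe size. Genes below the frequency threshold are dropped
#' (inclusive: a gene at exactly `min_freq` is retained) and the remainder
#' are ordered by descending frequency, ties by gene identifier.
#'
#' @param maf data frame of records from [read_maf()].
#' @param samples character vector: the sample-identifier universe (typically
#'   the expression-matched samples). Frequencies are computed over this
#'   universe.
#' @param min_freq minimum mutation frequency to retain a gene (default 1%).
#' @param barcode_length prefix length used to reconcile MAF barcodes with
#'   `samples`; `NULL` disables truncation.
#' @return binary genes-by-samples matrix. Records whose (truncated) barcode
#'   is not in `samples` are skipped; their count is reported as a warning.
#' @export
build_mutation_matrix <- function(maf, samples, min_freq = 0.01,
                                  barcode_length = NULL) {
  stopifnot(is.data.frame(maf),
            all(c("gene_symbol", "variant_classification",
                  "sample_barcode") %in% names(maf)))
  if (!length(samples)) stop("sample universe is empty", call. = FALSE)
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicated sample identifiers", call. = FALSE)
  if (!is.numeric(min_freq) || min_freq < 0 || min_freq > 1)
    stop("min_freq must be in [0, 1]", call. = FALSE)

  rec <- maf[classify_nonsilent(maf$variant_classification), , drop = FALSE]
  bc <- truncate_barcode(rec$sample_barcode, barcode_length)
  known <- bc %in% samples
  if (any(!known))
    warning(sum(!known), " record(s) with sample barcodes outside the universe skipped",
            call. = FALSE)
  rec <- rec[known, , drop = FALSE]
  bc <- bc[known]

  genes <- sort(unique(rec$gene_symbol))
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (nrow(rec))
    m[cbind(match(rec$gene_symbol, genes), match(bc, samples))] <- 1L

  freq <- rowMeans(m)
  keep <- freq >= min_freq
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(m)
  ord <- order(-freq[keep], rownames(m))
  m[ord, , drop = FALSE]
}

#' Per-gene mutation frequency of a binary mutation matrix
#'
#' @param mutations binary genes-by-samples matrix.
#' @return named numeric vector of row means.
#' @export
mutation_frequency <- function(mutations) {
  .assert_binary(mutations, "mutation matrix")
  rowMeans(mutations)
}
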