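# Native single-sample GSEA (ssGSEA) scorer: a rank-based per-sample score of
# a gene set's coordinate up-regulation, used here to turn bulk expression
# into a cells x samples relative abundance matrix.

#' Score gene sets per sample by single-sample GSEA
#'
#' For each sample, genes are ranked by descending expression (ties broken
#' deterministically by ascending gene identifier). For a set S over N genes
#' the enrichment score is the sum over positions i = 1..N of
#' \deqn{P_{hit}(i) - P_{miss}(i)}
#' where \eqn{P_{hit}(i)} is the weighted fraction of set genes at rank <= i,
#' weighting gene g by \eqn{(N - rank(g) + 1)^\alpha}, and \eqn{P_{miss}(i)}
#' is the unweighted fraction of non-set genes at rank <= i. Because only
#' ranks enter, scores are invariant to any per-sample strictly monotone
#' transform of expression (so raw, log or scaled units agree).
#'
#' Genes of a set absent from the expression matrix are dropped (a message
#' reports the count); a set with no gene present yields an `NA` row with a
#' warning. With `normalize = TRUE` the whole score matrix is divided by its
#' global max - min range.
#'
#' @param expr numeric genes-by-samples expression matrix.
#' @param sets named list of character vectors (e.g. from [read_gmt()]),
#'   one per cell type.
#' @param alpha rank-weight exponent, >= 0; `alpha = 0` gives the unweighted
#'   ECDF difference. Default 0.25.
#' @param normalize divide all scores by the global score range (default TRUE).
#' @return numeric cells-by-samples matrix of relative abundance scores.
#' @export
ssgsea_score <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  .assert_matrix(expr, "expression matrix")
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("alpha must be a finite non-negative scalar", call. = FALSE)
  N <- nrow(expr)
  genes <- rownames(expr)
  present <- lapply(sets, function(s) unique(s[s %in% genes]))
  dropped <- vapply(sets, length, 0L) - vapply(present, length, 0L)
  if (any(dropped > 0))
    message(sum(dropped), " signature gene(s) absent from the expression matrix dropped")
  sizes <- vapply(present, length, 0L)
  if (all(sizes == 0L)) stop("no gene set has any gene in the expression matrix",
                             call. = FALSE)
  if (any(sizes == N))
    stop("a gene set covers every expressed gene; complement is empty", call. = FALSE)
  if (any(sizes == 0L))
    warning(sum(sizes == 0L), " gene set(s) with no genes present scored as NA",
            call. = FALSE)

  w <- (N:1)^alpha                     # rank value weight at sorted position i
  cw <- cumsum(w)
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  # tie-break by ascending gene id: order by id first, then stable sort on value
  id_ord <- order(genes)
  for (j in seq_len(ncol(expr))) {
    o <- id_ord[order(-expr[id_ord, j], method = "radix")]  # descending expr
    pos <- integer(N); pos[o] <- seq_len(N)                 # gene -> rank
    for (k in seq_along(present)) {
      s <- present[[k]]
      if (!length(s)) next
      hit <- logical(N); hit[pos[match(s, genes)]] <- TRUE
      wh <- cumsum(w * hit) / sum(w[hit])
      mh <- (seq_len(N) - cumsum(hit)) / (N - length(s))
      scores[k, j] <- sum(wh - mh)
    }
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  scores
}
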