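# Core identification step: row z-scoring of dysregulated cells, binarization
# at |z| > 2, 2x2 Fisher exact association of mutation status with the binary
# cell response, BH correction, and per-gene orchestration. Also pairwise
# mutation co-occurrence / mutual exclusivity.

#' Row-wise z-scores
#'
#' Standardises each row to mean 0, sample SD 1 (denominator n - 1).
#' Constant rows become all zeros and are flagged in the `"constant_rows"`
#' attribute.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m), ncol(m) >= 2)
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  sdv[const] <- 1
  z <- (m - mu) / sdv
  z[const, ] <- 0
  attr(z, "constant_rows") <- rownames(m)[const]
  z
}

#' Binarize a z-scored abundance matrix into up/down response matrices
#'
#' Entry (i, j) of the `up` matrix is 1 when z(i, j) > `z_threshold` (strict)
#' and of the `down` matrix when z(i, j) <= -`z_threshold`; everything else is
#' 0. With a positive threshold the two matrices are disjoint by construction.
#'
#' @param z z-scored cells-by-samples matrix from [zscore_rows()].
#' @param z_threshold positive threshold (default 2.0).
#' @return list with binary matrices `up` and `down` and the threshold used.
#' @export
binarize <- function(z, z_threshold = 2.0) {
  stopifnot(is.matrix(z), is.numeric(z_threshold), z_threshold > 0)
  up <- (z > z_threshold) + 0
  down <- (z <= -z_threshold) + 0
  dimnames(up) <- dimnames(down) <- dimnames(z)
  list(up = up, down = down, z_threshold = z_threshold)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value is the minimum-likelihood summation: the total
#' hypergeometric probability of all tables with the observed margins whose
#' probability does not exceed the observed table's (within a relative slack
#' of 1e-7). The odds ratio is the sample estimate (a d)/(b c), `Inf` when
#' b c = 0 with a d > 0. A zero row or column margin is degenerate: p = 1
#' and odds ratio `NA`.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  if (a + b + cc + d == 0) stop("empty table", call. = FALSE)
  m1 <- a + b; m2 <- cc + d; k <- a + cc
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0)
    return(list(odds_ratio = NA_real_, p = 1))
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  pobs <- stats::dhyper(a, m1, m2, k)
  p <- min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
  or <- if (b * cc == 0) {
    if (a * d > 0) Inf else 0
  } else (a * d) / (b * cc)
  list(odds_ratio = or, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with m p-values sorted ascending,
#' q(i) = min over j >= i of p(j) m / j, capped at 1 and mapped back to the
#' input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Identify mutation-driven immune cells
#'
#' The central routine: for each mutated gene it (1) tests every cell's
#' abundance between mutated and wild-type samples with the permutation SAM
#' test, (2) z-scores the significantly dysregulated cells by row across all
#' samples and binarizes at the z threshold, (3) builds, per significant
#' cell, the 2x2 table of mutation status against the binary response taken
#' from the matrix matching the cell's SAM direction (up when d > 0, down
#' when d < 0) and applies the Fisher exact test, (4) adjusts the Fisher
#' p-values by Benjamini-Hochberg across the cells tested within that gene
#' (or globally across genes with `global_fdr = TRUE`), and (5) reports cells
#' with adjusted p below `fisher_fdr` as driven by the mutation.
#'
#' Both matrices are restricted to their shared samples (in the abundance
#' matrix's column order). Genes whose mutated or wild-type class has fewer
#' than 2 shared samples are skipped with a warning; genes with no
#' SAM-significant cell yield an empty (not missing) result.
#'
#' @param abundance numeric cells-by-samples matrix.
#' @param mutations binary genes-by-samples mutation matrix.
#' @param sam_fdr SAM q-value cut calling a cell dysregulated (default 0.05).
#' @param fisher_fdr adjusted Fisher p cut calling a cell driven (default 0.05).
#' @param z_threshold binarization threshold on row z-scores (default 2.0).
#' @param n_perm SAM permutation count (default 1000).
#' @param seed integer seed; per-gene permutation seeds are derived from it.
#' @param global_fdr apply the Fisher BH correction across all genes jointly
#'   instead of within gene.
#' @return an object of class `cell_assoc`: list with per-gene result tables
#'   (`genes`), a `summary` data frame (gene, driven cells, cell count,
#'   mutation rate) and the configuration used.
#' @export
find_driven_cells <- function(abundance, mutations, sam_fdr = 0.05,
                              fisher_fdr = 0.05, z_threshold = 2.0,
                              n_perm = 1000L, seed, global_fdr = FALSE) {
  .assert_matrix(abundance, "abundance matrix")
  .assert_binary(mutations, "mutation matrix")
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  shared <- colnames(abundance)[colnames(abundance) %in% colnames(mutations)]
  if (!length(shared)) stop("no shared samples between matrices", call. = FALSE)
  if (length(shared) < 20)
    stop("fewer than 20 shared samples; association is not meaningful",
         call. = FALSE)
  if (length(shared) < 50)
    warning("fewer than 50 shared samples; results will be unstable", call. = FALSE)
  ab <- abundance[, shared, drop = FALSE]
  mut <- mutations[, shared, drop = FALSE]
  freq <- rowMeans(mut)

  results <- vector("list", nrow(mut))
  names(results) <- rownames(mut)
  for (gi in seq_len(nrow(mut))) {
    gene <- rownames(mut)[gi]
    lab <- mut[gi, ]
    if (sum(lab == 1) < 2 || sum(lab == 0) < 2) {
      warning("gene ", gene, " skipped: a mutation class has < 2 samples",
              call. = FALSE)
      results[[gi]] <- .empty_gene_result()
      next
    }
    sam <- sam_test(ab, lab, n_perm = n_perm,
                    seed = .derive_seed(seed, gi), fdr_cut = sam_fdr)
    sig <- names(sam$significant)[sam$significant & sam$direction != 0]
    if (!length(sig)) {
      results[[gi]] <- .empty_gene_result()
      next
    }
    z <- zscore_rows(ab[sig, , drop = FALSE])
    bin <- binarize(z, z_threshold)
    rows <- lapply(sig, function(cell) {
      resp <- if (sam$d[cell] > 0) bin$up[cell, ] else bin$down[cell, ]
      tab <- matrix(c(sum(lab == 1 & resp == 1), sum(lab == 1 & resp == 0),
                      sum(lab == 0 & resp == 1), sum(lab == 0 & resp == 0)),
                    nrow = 2L, byrow = TRUE)
      ft <- fisher_exact_2x2(tab)
      data.frame(cell = cell,
                 direction = if (sam$d[cell] > 0) "up" else "down",
                 odds_ratio = ft$odds_ratio, p = ft$p,
                 sam_d = unname(sam$d[cell]), sam_q = unname(sam$q[cell]),
                 stringsAsFactors = FALSE)
    })
    tabr <- do.call(rbind, rows)
    tabr$fdr <- NA_real_
    results[[gi]] <- tabr
  }

  # BH across Fisher p-values, per gene or pooled across genes
  if (global_fdr) {
    all_p <- unlist(lapply(results, function(r) r$p))
    all_q <- if (length(all_p)) bh_adjust(all_p) else numeric(0)
    at <- 0L
    for (gi in seq_along(results)) {
      nr <- nrow(results[[gi]])
      if (nr) {
        results[[gi]]$fdr <- all_q[at + seq_len(nr)]
        at <- at + nr
      }
    }
  } else {
    for (gi in seq_along(results))
      if (nrow(results[[gi]]))
        results[[gi]]$fdr <- bh_adjust(results[[gi]]$p)
  }
  for (gi in seq_along(results)) {
    r <- results[[gi]]
    r$driven <- if (nrow(r)) r$fdr < fisher_fdr else logical(0)
    results[[gi]] <- r[order(r$p, r$cell), , drop = FALSE]
  }

  summary_df <- do.call(rbind, lapply(seq_along(results), function(gi) {
    r <- results[[gi]]
    cells <- r$cell[r$driven]
    data.frame(gene = names(results)[gi],
               cells = paste(sort(cells), collapse = ", "),
               cell_count = length(cells),
               mutation_rate = unname(freq[gi]),
               stringsAsFactors = FALSE)
  }))
  summary_df <- summary_df[order(-summary_df$cell_count, summary_df$gene), ,
                           drop = FALSE]
  rownames(summary_df) <- NULL

  structure(list(genes = results, summary = summary_df,
                 samples = shared,
                 config = list(sam_fdr = sam_fdr, fisher_fdr = fisher_fdr,
                               z_threshold = z_threshold,
                               n_perm = as.integer(n_perm), seed = seed,
                               global_fdr = global_fdr)),
            class = "cell_assoc")
}

.empty_gene_result <- function() {
  data.frame(cell = character(0), direction = character(0),
             odds_ratio = numeric(0), p = numeric(0), sam_d = numeric(0),
             sam_q = numeric(0), fdr = numeric(0), driven = logical(0),
             stringsAsFactors = FALSE)
}

#' Driven (gene, cell) pairs of a `cell_assoc` object
#'
#' @param assoc object from [find_driven_cells()].
#' @return data frame with columns `gene`, `cell`, `direction`.
#' @export
driven_pairs <- function(assoc) {
  stopifnot(inherits(assoc, "cell_assoc"))
  out <- do.call(rbind, lapply(names(assoc$genes), function(g) {
    r <- assoc$genes[[g]]
    r <- r[r$driven, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    data.frame(gene = g, cell = r$cell, direction = r$direction,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(gene = character(0), cell = character(0),
                      direction = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.cell_assoc <- function(x, ...) {
  cat("Mutation-driven immune cell identification\n")
  cat(sprintf("  %d gene(s), %d sample(s); SAM q < %g, Fisher FDR < %g, |z| > %g\n",
              length(x$genes), length(x$samples), x$config$sam_fdr,
              x$config$fisher_fdr, x$config$z_threshold))
  hit <- x$summary[x$summary$cell_count > 0, , drop = FALSE]
  cat(sprintf("  %d gene(s) with driven cells\n", nrow(hit)))
  if (nrow(hit)) print(utils::head(hit, 10), row.names = FALSE)
  invisible(x)
}

#' @export
summary.cell_assoc <- function(object, ...) object$summary

#' Pairwise mutation co-occurrence and mutual exclusivity
#'
#' For every unordered pair of genes, builds the 2x2 table of joint mutation
#' status across samples and applies the Fisher exact test. A pair is labelled
#' co-occurring when the odds ratio exceeds 1 with p < `alpha`, mutually
#' exclusive when the odds ratio is below 1 with p < `alpha`, and `none`
#' otherwise.
#'
#' @param mutations binary genes-by-samples matrix.
#' @param genes gene subset to test (default: all rows); needs >= 2.
#' @param alpha significance level (default 0.05).
#' @return object of class `cooc_result`: data frame with `gene_a`, `gene_b`,
#'   `odds_ratio`, `p`, `label`.
#' @export
cooc_mutex <- function(mutations, genes = rownames(mutations), alpha = 0.05) {
  .assert_binary(mutations, "mutation matrix")
  genes <- as.character(genes)
  if (length(genes) < 2) stop("need at least 2 genes", call. = FALSE)
  missing <- setdiff(genes, rownames(mutations))
  if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "),
                            call. = FALSE)
  pairs <- utils::combn(genes, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    va <- mutations[ga, ]; vb <- mutations[gb, ]
    tab <- matrix(c(sum(va == 1 & vb == 1), sum(va == 1 & vb == 0),
                    sum(va == 0 & vb == 1), sum(va == 0 & vb == 0)),
                  nrow = 2L, byrow = TRUE)
    ft <- fisher_exact_2x2(tab)
    label <- if (is.na(ft$odds_ratio) || ft$p >= alpha) "none"
             else if (ft$odds_ratio > 1) "co-occurring"
             else if (ft$odds_ratio < 1) "mutually exclusive"
             else "none"
    data.frame(gene_a = ga, gene_b = gb, odds_ratio = ft$odds_ratio,
               p = ft$p, label = label, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("cooc_result", "data.frame")
  out
}
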