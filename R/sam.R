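# Two-class unpaired SAM (significance analysis of microarrays): a moderated
# t-like statistic d = (mean1 - mean0) / (s + s0) with a data-driven fudge
# factor s0 and a pooled permutation null giving per-feature p-values, here
# applied to immune-cell abundance rows against a binary mutation vector.

# per-row difference of class means and Tusher pooled scatter s, vectorised
# over the rows of X (features x samples); lab is 0/1 per sample.
.sam_parts <- function(X, lab) {
  lab <- as.numeric(lab)
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  if (n1 < 2 || n0 < 2) stop("insufficient class size", call. = FALSE)
  m1 <- X %*% (lab / n1)
  m0 <- X %*% ((1 - lab) / n0)
  ss1 <- (X * X) %*% lab - n1 * m1 * m1
  ss0 <- (X * X) %*% (1 - lab) - n0 * m0 * m0
  s <- sqrt((1 / n1 + 1 / n0) / (n1 + n0 - 2) * pmax(ss1 + ss0, 0))
  list(diff = as.vector(m1 - m0), s = as.vector(s), n1 = n1, n0 = n0)
}

#' SAM moderated test statistic for one feature
#'
#' Computes d = (mean of class 1 - mean of class 0) / (s + s0), where s is
#' the pooled scatter
#' \deqn{s = \sqrt{\frac{1/n_1 + 1/n_0}{n_1 + n_0 - 2}
#'   \left(\sum_{1}(x - \bar x_1)^2 + \sum_{0}(x - \bar x_0)^2\right)}}
#' and s0 is the fudge factor stabilising low-variance features. Class 1 is
#' the mutated group, so d > 0 means higher abundance with mutation.
#'
#' @param values numeric vector, one value per sample.
#' @param labels 0/1 vector of class membership (1 = mutated); both classes
#'   need at least 2 samples.
#' @param s0 fudge factor, >= 0.
#' @return the statistic d (a scalar).
#' @export
sam_statistic <- function(values, labels, s0 = 0) {
  stopifnot(length(values) == length(labels), is.numeric(s0), s0 >= 0)
  p <- .sam_parts(matrix(values, nrow = 1L), labels)
  p$diff / (p$s + s0)
}

# candidate-wise coefficient of variation of windowed MADs of d, the
# criterion minimised by the Tusher s0 search
.s0_cv <- function(diff, s, s0, n_windows) {
  d <- diff / (s + s0)
  win <- as.integer(cut(rank(s, ties.method = "first"),
                        breaks = n_windows, labels = FALSE))
  mads <- tapply(d, win, stats::mad)
  mu <- mean(mads)
  if (!is.finite(mu) || mu == 0) return(Inf)
  stats::sd(mads) / mu
}

#' Estimate the SAM fudge factor s0
#'
#' Tusher-style search: candidates are 0 together with the 0, 5, ..., 100
#' percentiles of the per-feature pooled scatters s; the chosen s0 minimises
#' the coefficient of variation of the median absolute deviation of d taken
#' across windows of features grouped by s quantiles. Deterministic; ties go
#' to the smallest candidate.
#'
#' @param abundance numeric features-by-samples matrix (cells x samples).
#' @param labels 0/1 class vector, one per sample.
#' @return the selected s0 (scalar). With a single feature, falls back to
#'   `median(s)` with a warning; if all s are identical, returns that value.
#' @export
estimate_s0 <- function(abundance, labels) {
  .assert_matrix(abundance, "abundance matrix")
  parts <- .sam_parts(abundance, labels)
  s <- parts$s
  n <- length(s)
  if (n < 5) warning("fewer than 5 features; s0 estimate is unstable", call. = FALSE)
  if (n == 1L) {
    warning("single feature: s0 set to median(s)", call. = FALSE)
    return(stats::median(s))
  }
  if (diff(range(s)) == 0) return(s[1L])
  cand <- sort(unique(c(0, unname(stats::quantile(s, seq(0, 1, by = 0.05))))))
  n_windows <- max(2L, min(10L, floor(n / 5)))
  cv <- vapply(cand, function(s0) .s0_cv(parts$diff, s, s0, n_windows), 0)
  cand[which.min(cv)]
}

#' Permutation SAM test of cell abundance against mutation status
#'
#' Computes the observed SAM statistic for every abundance row, then builds a
#' pooled permutation null by recomputing all statistics under `n_perm`
#' random permutations of the class labels (s0 held fixed at its observed
#' estimate). The per-row p-value is
#' `(1 + #\{null |d*| >= |d|\}) / (1 + n_perm * n_cells)` and q-values are
#' Benjamini-Hochberg over rows; rows with q below `fdr_cut` are called
#' significantly dysregulated, with direction `sign(d)`.
#'
#' @param abundance numeric cells-by-samples matrix.
#' @param labels 0/1 mutation vector per sample (needs >= 2 of each class).
#' @param n_perm number of label permutations (>= 100; default 1000).
#' @param seed integer seed; required for reproducibility.
#' @param fdr_cut q-value threshold for significance (default 0.05).
#' @param s0 optional fixed fudge factor; estimated by [estimate_s0()] when
#'   `NULL`.
#' @return an object of class `sam_result`: a list with `cell_ids`, `d`, `p`,
#'   `q`, `direction`, `significant`, `s0`, `n_perm`.
#' @export
sam_test <- function(abundance, labels, n_perm = 1000L, seed, fdr_cut = 0.05,
                     s0 = NULL) {
  .assert_matrix(abundance, "abundance matrix")
  stopifnot(ncol(abundance) == length(labels), all(labels %in% c(0, 1)))
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2)
    stop("too few samples in a mutation class; consider a higher min_freq",
         call. = FALSE)
  # canonical sample order, so results are invariant under identical
  # permutations of both inputs (the permutation null is drawn over a fixed
  # arrangement)
  ord <- order(colnames(abundance))
  abundance <- abundance[, ord, drop = FALSE]
  labels <- labels[ord]
  n_cells <- nrow(abundance)
  parts <- .sam_parts(abundance, labels)
  if (is.null(s0))
    s0 <- if (n_cells == 1L) {
      warning("single feature: s0 set to its own s", call. = FALSE)
      parts$s
    } else suppressWarnings(estimate_s0(abundance, labels))
  d <- parts$diff / (parts$s + s0)

  n <- length(labels)
  n1 <- parts$n1
  set.seed(as.integer(seed) %% 2147483647L)
  # permuted label matrix: each column one permutation (class sizes preserved)
  L <- vapply(seq_len(n_perm), function(i) {
    v <- numeric(n); v[sample.int(n, n1)] <- 1; v
  }, numeric(n))
  m1 <- (abundance %*% L) / n1
  m0 <- (abundance %*% (1 - L)) / (n - n1)
  sq <- abundance * abundance
  ss1 <- sq %*% L - n1 * m1 * m1
  ss0 <- sq %*% (1 - L) - (n - n1) * m0 * m0
  s_null <- sqrt((1 / n1 + 1 / (n - n1)) / (n - 2) * pmax(ss1 + ss0, 0))
  d_null <- as.vector(abs((m1 - m0) / (s_null + s0)))

  total <- n_perm * n_cells
  ge <- vapply(abs(d), function(a) sum(d_null >= a), 0)
  p <- (1 + ge) / (1 + total)
  q <- bh_adjust(p)
  structure(list(
    cell_ids = rownames(abundance),
    d = stats::setNames(d, rownames(abundance)),
    p = stats::setNames(p, rownames(abundance)),
    q = stats::setNames(q, rownames(abundance)),
    direction = stats::setNames(sign(d), rownames(abundance)),
    significant = stats::setNames(q < fdr_cut, rownames(abundance)),
    s0 = s0, n_perm = as.integer(n_perm), fdr_cut = fdr_cut
  ), class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM permutation test:", length(x$d), "cells,", x$n_perm,
      "permutations, s0 =", signif(x$s0, 4), "\n")
  sig <- names(x$significant)[x$significant]
  cat(sum(x$significant), "significant at q <", x$fdr_cut)
  if (length(sig)) cat(":", paste(sig, collapse = ", "))
  cat("\n")
  invisible(x)
}
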