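# Synthetic cohort generator with known ground truth: Bernoulli mutation
# status per gene, Gaussian baseline cell abundances with planted mean
# shifts in mutated samples, exponential survival tied to planted Cox
# coefficients, and (optionally) an expression matrix whose signature genes
# track each cell's abundance so the full expression -> cells path can be
# exercised. Also the gene-dropout robustness experiment.

#' Planted ground truth for a synthetic cohort
#'
#' @param planted data frame with columns `gene` (index or name of the
#'   mutated gene), `cell` (index or name of the responding cell),
#'   `direction` (+1/-1) and `effect` (shift in baseline SD units, > 0).
#'   `NULL` plants nothing (a null cohort).
#' @param mut_freq per-gene mutation frequency in (0, 1); recycled.
#' @param surv_beta named-by-cell-index numeric vector of true Cox log-hazard
#'   coefficients; `NULL` for survival independent of abundance.
#' @param censor_rate approximate fraction of censored samples.
#' @return a `cohort_truth` list.
#' @export
cohort_truth <- function(planted = NULL, mut_freq = 0.2, surv_beta = NULL,
                         censor_rate = 0.3) {
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("gene", "cell", "direction", "effect") %in% names(planted)),
              all(planted$effect > 0), all(planted$direction %in% c(-1, 1)))
  }
  stopifnot(all(mut_freq > 0 & mut_freq < 1),
            censor_rate >= 0, censor_rate < 1)
  structure(list(planted = planted, mut_freq = mut_freq,
                 surv_beta = surv_beta, censor_rate = censor_rate),
            class = "cohort_truth")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Mutation status of each gene is iid Bernoulli at its planted frequency;
#' baseline cell abundances are standard normal per cell; each planted
#' (gene, cell, direction, effect) shifts that cell's abundance by
#' `direction * effect` SD units in the gene's mutated samples. Survival
#' times are exponential with hazard `exp(sum(beta_c * a_c))` and independent
#' exponential censoring calibrated to the requested censoring fraction.
#' With `expression = TRUE` a genes-by-samples expression matrix and matching
#' gene-set collection are also generated: each cell has `genes_per_set`
#' signature genes whose expression is unit Gaussian noise plus
#' `coupling * abundance`, plus unrelated background genes whose per-gene
#' dispersions are drawn from `noise_dispersion` (log-scale expression shows
#' wide between-gene dispersion differences; keeping signature shifts
#' comparable to the background spread also keeps the rank-based scorer in
#' its linear regime instead of saturating its running sum).
#'
#' @param n_samples number of samples (>= 20).
#' @param n_cells number of cell types.
#' @param n_genes number of mutated genes.
#' @param truth a [cohort_truth()]; its planted gene/cell indices must be in
#'   range.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param expression also generate an expression matrix and GMT sets.
#' @param genes_per_set signature size per cell (expression mode).
#' @param n_noise_genes unrelated background genes added to the expression
#'   matrix.
#' @param coupling abundance-to-signature-expression coupling (expression mode).
#' @param noise_dispersion range of per-gene SDs for the background genes.
#' @return list with `abundance` (cells x samples), `mutations` (binary genes
#'   x samples), `survival` (data frame), `truth`, and, in expression mode,
#'   `expression` and `gene_sets`.
#' @export
generate_cohort <- function(n_samples, n_cells, n_genes,
                            truth = cohort_truth(), seed,
                            expression = FALSE, genes_per_set = 10L,
                            n_noise_genes = 10L * n_cells, coupling = 1,
                            noise_dispersion = c(0.5, 4)) {
  stopifnot(n_samples >= 20, n_cells >= 1, n_genes >= 1)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(as.integer(seed) %% 2147483647L)

  samples <- sprintf("S%04d", seq_len(n_samples))
  cells <- sprintf("cell%02d", seq_len(n_cells))
  genes <- sprintf("G%03d", seq_len(n_genes))

  freq <- rep_len(truth$mut_freq, n_genes)
  mut <- matrix(stats::rbinom(n_genes * n_samples, 1L, rep(freq, n_samples)),
                nrow = n_genes, dimnames = list(genes, samples))
  ab <- matrix(stats::rnorm(n_cells * n_samples), nrow = n_cells,
               dimnames = list(cells, samples))

  planted <- truth$planted
  if (!is.null(planted) && nrow(planted)) {
    gi <- .resolve_index(planted$gene, genes, "gene")
    ci <- .resolve_index(planted$cell, cells, "cell")
    for (k in seq_len(nrow(planted))) {
      hit <- mut[gi[k], ] == 1
      ab[ci[k], hit] <- ab[ci[k], hit] + planted$direction[k] * planted$effect[k]
    }
    planted$gene <- genes[gi]
    planted$cell <- cells[ci]
  }

  beta <- rep(0, n_cells)
  if (!is.null(truth$surv_beta)) {
    bi <- .resolve_index(names(truth$surv_beta) %||% seq_along(truth$surv_beta),
                         cells, "cell")
    beta[bi] <- as.numeric(truth$surv_beta)
  }
  lp <- drop(beta %*% ab)
  t_event <- stats::rexp(n_samples, rate = exp(lp))
  cr <- truth$censor_rate
  if (cr > 0) {
    t_cens <- stats::rexp(n_samples, rate = cr / (1 - cr) * exp(mean(lp)))
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n_samples)
  }
  surv <- data.frame(sample = samples, time = time, event = event,
                     stringsAsFactors = FALSE)

  out <- list(abundance = ab, mutations = mut, survival = surv,
              truth = structure(c(truth, list(planted_resolved = planted,
                                              beta_cells = stats::setNames(beta, cells),
                                              seed = seed)),
                                class = "cohort_truth"))
  if (expression) {
    sig_genes <- paste0(rep(cells, each = genes_per_set), "_sig",
                        seq_len(genes_per_set))
    noise_genes <- sprintf("noise%04d", seq_len(n_noise_genes))
    noise_sd <- stats::runif(n_noise_genes, noise_dispersion[1],
                             noise_dispersion[2])
    expr <- matrix(stats::rnorm((length(sig_genes) + n_noise_genes) * n_samples,
                                sd = rep(c(rep(1, length(sig_genes)), noise_sd),
                                         n_samples)),
                   nrow = length(sig_genes) + n_noise_genes,
                   dimnames = list(c(sig_genes, noise_genes), samples))
    for (k in seq_len(n_cells)) {
      idx <- (k - 1L) * genes_per_set + seq_len(genes_per_set)
      expr[idx, ] <- expr[idx, ] + coupling * rep(ab[k, ], each = genes_per_set)
    }
    out$expression <- expr
    out$gene_sets <- stats::setNames(
      lapply(seq_len(n_cells), function(k)
        sig_genes[(k - 1L) * genes_per_set + seq_len(genes_per_set)]),
      cells)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolve_index <- function(x, universe, what) {
  if (is.numeric(x)) {
    idx <- as.integer(x)
    if (any(idx < 1 | idx > length(universe)))
      stop("planted ", what, " index out of range", call. = FALSE)
    return(idx)
  }
  idx <- match(as.character(x), universe)
  if (anyNA(idx)) stop("unknown planted ", what, call. = FALSE)
  idx
}

#' Randomly drop a fraction of genes from an expression matrix
#'
#' Removes a uniformly random subset of `round(fraction * n_genes)` genes.
#' Implemented as a prefix of one seeded permutation, so for a fixed seed the
#' removed sets are nested across increasing fractions (coupled sampling,
#' which reduces Monte-Carlo variance of robustness curves).
#'
#' @param expr genes-by-samples matrix.
#' @param fraction fraction of genes to remove, in \[0, 1).
#' @param seed integer seed.
#' @return the reduced matrix, original row order preserved.
#' @export
dropout_genes <- function(expr, fraction, seed) {
  .assert_matrix(expr, "expression matrix")
  stopifnot(fraction >= 0, fraction < 1)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  n_drop <- round(fraction * nrow(expr))
  if (n_drop == 0) return(expr)
  set.seed(as.integer(seed) %% 2147483647L)
  perm <- sample.int(nrow(expr))
  keep <- sort(perm[-seq_len(n_drop)])
  expr[keep, , drop = FALSE]
}

#' Per-gene overlap of driven-cell sets between two runs
#'
#' For each gene with at least one driven cell in the baseline result `a`,
#' computes `|cells_a intersect cells_b| / |cells_a|`. Genes absent from the
#' comparison result contribute 0; genes with no baseline cells are skipped.
#'
#' @param result_a baseline `cell_assoc` (full data).
#' @param result_b comparison `cell_assoc` (e.g. after gene dropout).
#' @return named numeric vector of per-gene overlap fractions in \[0, 1\].
#' @export
overlap_score <- function(result_a, result_b) {
  pa <- driven_pairs(result_a)
  pb <- driven_pairs(result_b)
  genes <- unique(pa$gene)
  out <- vapply(genes, function(g) {
    ca <- pa$cell[pa$gene == g]
    cb <- pb$cell[pb$gene == g]
    length(intersect(ca, cb)) / length(ca)
  }, 0)
  stats::setNames(out, genes)
}
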