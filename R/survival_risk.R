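# Immune-cell risk score: multivariate Cox coefficients over the driven
# cells, per-sample risk score sum(beta_k * a_k), median split into high/low
# risk groups, and the log-rank comparison of the two groups.

.align_survival <- function(abundance_subset, survival) {
  stopifnot(is.data.frame(survival),
            all(c("sample", "time", "event") %in% names(survival)))
  shared <- colnames(abundance_subset)[colnames(abundance_subset) %in%
                                         survival$sample]
  if (!length(shared)) stop("no samples shared with the survival table",
                            call. = FALSE)
  list(ab = abundance_subset[, shared, drop = FALSE],
       surv = survival[match(shared, survival$sample), , drop = FALSE])
}

#' Fit the multivariate Cox model over a cell panel
#'
#' Maximises the Cox partial likelihood of overall survival on the abundances
#' of the given cells (one covariate per cell), with Breslow tie handling by
#' default. Zero-variance cells are dropped with a warning; exactly collinear
#' cells are resolved by dropping the later-indexed duplicates.
#'
#' @param abundance_subset cells-by-samples matrix restricted to the cell
#'   signature S.
#' @param survival data frame with `sample`, `time`, `event`; samples are
#'   matched to the matrix columns.
#' @param ties tie-handling method, `"breslow"` (default) or `"efron"`.
#' @return named numeric vector of coefficients beta (log hazard per
#'   abundance unit), with the fitted `survival::coxph` object in the
#'   `"fit"` attribute.
#' @export
fit_cox <- function(abundance_subset, survival, ties = c("breslow", "efron")) {
  .assert_matrix(abundance_subset, "abundance matrix")
  ties <- match.arg(ties)
  al <- .align_survival(abundance_subset, survival)
  ab <- al$ab; sv <- al$surv
  if (sum(sv$event) < 10)
    warning("fewer than 10 events; coefficient estimates will be unstable",
            call. = FALSE)
  sdv <- apply(ab, 1L, stats::sd)
  if (any(sdv == 0)) {
    warning("dropping zero-variance cell(s): ",
            paste(rownames(ab)[sdv == 0], collapse = ", "), call. = FALSE)
    ab <- ab[sdv > 0, , drop = FALSE]
  }
  if (!nrow(ab)) stop("no cells left to fit", call. = FALSE)
  X <- t(ab)
  # drop later-indexed exactly collinear columns
  qr_x <- qr(cbind(1, X))
  if (qr_x$rank < ncol(X) + 1L) {
    keep_idx <- sort(setdiff(qr_x$pivot[seq_len(qr_x$rank)], 1L) - 1L)
    warning("dropping collinear cell(s): ",
            paste(colnames(X)[-keep_idx], collapse = ", "), call. = FALSE)
    X <- X[, keep_idx, drop = FALSE]
  }
  fit <- survival::coxph(
    survival::Surv(sv$time, sv$event) ~ X, ties = ties,
    control = survival::coxph.control(iter.max = 100, eps = 1e-9)
  )
  if (!is.null(fit$info) && isTRUE(grepl("Ran out of iterations", fit$info)))
    stop("Cox fit did not converge; try fewer cells", call. = FALSE)
  beta <- stats::coef(fit)
  if (anyNA(beta)) stop("Cox fit produced undefined coefficients", call. = FALSE)
  names(beta) <- colnames(X)
  attr(beta, "fit") <- fit
  beta
}

#' Per-sample immune-cell risk scores
#'
#' The risk score of sample j is the linear predictor
#' \deqn{\mathrm{score}_j = \sum_{k \in S} \beta_k a_{kj}}
#' over the cell signature S.
#'
#' @param beta named coefficient vector from [fit_cox()].
#' @param abundance_subset cells-by-samples matrix containing every cell in
#'   `names(beta)`.
#' @return named numeric vector of per-sample scores.
#' @export
risk_scores <- function(beta, abundance_subset) {
  .assert_matrix(abundance_subset, "abundance matrix")
  cells <- names(beta)
  if (is.null(cells) || !all(cells %in% rownames(abundance_subset)))
    stop("coefficient names do not match abundance rows", call. = FALSE)
  drop(as.numeric(beta) %*% abundance_subset[cells, , drop = FALSE])
}

#' Split samples into high/low risk at the median score
#'
#' Scores strictly above the median are `high`; scores at or below the
#' median (including ties at the median) are `low`.
#'
#' @param scores named numeric vector of risk scores (>= 4 samples).
#' @return named factor with levels `low`, `high`.
#' @export
median_split <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 4)
  if (diff(range(scores)) == 0)
    stop("degenerate signature: all risk scores identical", call. = FALSE)
  med <- stats::median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Two-group log-rank test
#'
#' @param groups factor of group membership, named by sample.
#' @param survival data frame with `sample`, `time`, `event`.
#' @return list with `chi_square` (1 df) and `p`.
#' @export
log_rank <- function(groups, survival) {
  stopifnot(!is.null(names(groups)))
  sv <- survival[match(names(groups), survival$sample), , drop = FALSE]
  if (anyNA(sv$sample)) stop("samples missing from the survival table", call. = FALSE)
  g <- factor(groups)
  if (nlevels(droplevels(g)) < 2) stop("both groups must be non-empty", call. = FALSE)
  if (sum(sv$event) < 1) stop("no events observed", call. = FALSE)
  sd0 <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ g)
  chi <- unname(sd0$chisq)
  list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Immune-cell risk signature for a mutated gene
#'
#' Builds the full prognostic signature from the cells driven by one gene:
#' fits the multivariate Cox model on those cells' abundances, computes the
#' per-sample risk scores, splits patients at the median score into high- and
#' low-risk groups, and compares the groups by the log-rank test.
#'
#' @param abundance cells-by-samples abundance matrix.
#' @param cells character vector: the driven-cell signature S (e.g. from
#'   [driven_pairs()] for one gene).
#' @param survival survival data frame (`sample`, `time`, `event`).
#' @param gene optional gene label carried in the result.
#' @param zscore use row z-scored abundances instead of raw values.
#' @param ties Cox tie handling, passed to [fit_cox()].
#' @return object of class `cell_risk` with elements `gene`, `cells`, `beta`,
#'   `risk_scores`, `groups`, `log_rank`, `survfit`, `survival`.
#' @export
cell_risk_model <- function(abundance, cells, survival, gene = NA_character_,
                            zscore = FALSE, ties = "breslow") {
  .assert_matrix(abundance, "abundance matrix")
  cells <- as.character(cells)
  if (!length(cells)) stop("empty cell signature", call. = FALSE)
  missing <- setdiff(cells, rownames(abundance))
  if (length(missing)) stop("cells absent from abundance matrix: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  ab <- abundance[cells, , drop = FALSE]
  if (zscore) ab <- zscore_rows(ab)
  al <- .align_survival(ab, survival)
  beta <- fit_cox(al$ab, al$surv, ties = ties)
  scores <- risk_scores(beta, al$ab)
  names(scores) <- colnames(al$ab)
  groups <- median_split(scores)
  names(groups) <- names(scores)
  lr <- log_rank(groups, al$surv)
  sf <- survival::survfit(survival::Surv(al$surv$time, al$surv$event) ~ groups)
  structure(list(gene = gene, cells = names(beta), beta = beta,
                 risk_scores = scores, groups = groups, log_rank = lr,
                 survfit = sf, survival = al$surv),
            class = "cell_risk")
}

#' @export
print.cell_risk <- function(x, ...) {
  cat("Immune-cell risk signature",
      if (!is.na(x$gene)) paste0("for ", x$gene), "\n")
  cat("  cells:", paste(x$cells, collapse = ", "), "\n")
  cat("  groups:", sum(x$groups == "high"), "high /",
      sum(x$groups == "low"), "low risk\n")
  cat(sprintf("  log-rank chi-square = %.3f, p = %.3g\n",
              x$log_rank$chi_square, x$log_rank$p))
  invisible(x)
}

#' @export
coef.cell_risk <- function(object, ...) {
  b <- object$beta
  attr(b, "fit") <- NULL
  b
}

#' Predict risk scores for new samples
#'
#' @param object a `cell_risk` model.
#' @param newdata cells-by-samples abundance matrix containing the model's
#'   cells; defaults to the training scores.
#' @param ... unused.
#' @return named numeric vector of risk scores.
#' @export
predict.cell_risk <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$risk_scores)
  risk_scores(coef(object), newdata)
}

#' @export
summary.cell_risk <- function(object, ...) {
  data.frame(sample = names(object$risk_scores),
             risk_score = unname(object$risk_scores),
             group = as.character(object$groups),
             stringsAsFactors = FALSE)
}
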