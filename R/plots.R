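# The four plot types: mutation waterfall (oncoprint), co-occurrence /
# mutual-exclusivity grid, mutation-vs-cell-abundance heat map, and
# Kaplan-Meier curves. Every plot writes an image plus a companion
# `<path>.layout.tsv` with the exact data drawn, and returns that layout
# table invisibly so tests can assert on data rather than pixels.

#' Plot output specification
#'
#' @param path output file path.
#' @param format one of `png`, `pdf`, `svg`; inferred from the file
#'   extension when `NULL`.
#' @param width,height device size in inches.
#' @param dpi resolution for raster output.
#' @return a `plot_spec` list.
#' @export
plot_spec <- function(path, format = NULL, width = 7, height = 5, dpi = 150) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("png", "pdf", "svg"))
  stopifnot(width > 0, height > 0, dpi > 0)
  structure(list(path = path, format = format, width = width,
                 height = height, dpi = dpi), class = "plot_spec")
}

.open_device <- function(spec) {
  switch(spec$format,
    png = grDevices::png(spec$path, width = spec$width, height = spec$height,
                         units = "in", res = spec$dpi),
    pdf = grDevices::pdf(spec$path, width = spec$width, height = spec$height),
    svg = grDevices::svg(spec$path, width = spec$width, height = spec$height))
}

.write_layout <- function(layout, spec) {
  utils::write.table(layout, paste0(spec$path, ".layout.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(layout)
}

#' Mutation waterfall (oncoprint) plot
#'
#' Genes as rows sorted by descending mutation frequency; samples as columns
#' in memo-sort order (presence of the most frequent gene first, then the
#' next, ...), the standard oncoprint convention. A per-gene frequency bar is
#' drawn on the right.
#'
#' @param mutations binary genes-by-samples matrix.
#' @param genes gene subset to draw (default all).
#' @param spec a [plot_spec()].
#' @return invisibly, the layout table (gene, sample, row, col, mutated).
#' @export
plot_waterfall <- function(mutations, genes = rownames(mutations), spec) {
  .assert_binary(mutations, "mutation matrix")
  genes <- as.character(genes)
  if (!length(genes)) stop("empty gene list", call. = FALSE)
  missing <- setdiff(genes, rownames(mutations))
  if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "),
                            call. = FALSE)
  m <- mutations[genes, , drop = FALSE]
  freq <- rowMeans(m)
  gene_ord <- order(-freq, rownames(m))
  m <- m[gene_ord, , drop = FALSE]
  # memo sort: lexicographic on columns, higher-frequency genes first
  keys <- c(lapply(seq_len(nrow(m)), function(i) -m[i, ]),
            list(colnames(m)))
  samp_ord <- do.call(order, keys)
  m <- m[, samp_ord, drop = FALSE]

  layout <- data.frame(
    gene = rep(rownames(m), times = ncol(m)),
    sample = rep(colnames(m), each = nrow(m)),
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    mutated = as.integer(m),
    stringsAsFactors = FALSE
  )
  .open_device(spec)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::layout(matrix(1:2, nrow = 1), widths = c(4, 1))
  graphics::par(mar = c(4, 6, 2, 0.5))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ,
                  drop = FALSE]),
                  col = c("grey92", "firebrick"), axes = FALSE,
                  xlab = "samples", ylab = "")
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.7, tick = FALSE)
  graphics::title(main = "Mutation waterfall")
  graphics::par(mar = c(4, 0.5, 2, 2))
  graphics::barplot(rev(rowMeans(m)), horiz = TRUE, names.arg = "",
                    col = "steelblue", xlab = "frequency")
  .write_layout(layout, spec)
}

#' Co-occurrence / mutual-exclusivity grid
#'
#' Lower-triangular grid over gene pairs coloured by -log10(p) signed by the
#' odds-ratio direction (positive = co-occurring, negative = mutually
#' exclusive).
#'
#' @param cooc a `cooc_result` from [cooc_mutex()].
#' @param spec a [plot_spec()].
#' @return invisibly, the layout table.
#' @export
plot_cooc_mutex <- function(cooc, spec) {
  stopifnot(inherits(cooc, "cooc_result"), nrow(cooc) >= 1)
  genes <- sort(unique(c(cooc$gene_a, cooc$gene_b)))
  sgn <- ifelse(is.na(cooc$odds_ratio), 0, ifelse(cooc$odds_ratio >= 1, 1, -1))
  val <- sgn * -log10(pmax(cooc$p, 1e-300))
  layout <- data.frame(gene_a = cooc$gene_a, gene_b = cooc$gene_b,
                       odds_ratio = cooc$odds_ratio, p = cooc$p,
                       label = cooc$label, signed_log10p = val,
                       stringsAsFactors = FALSE)
  n <- length(genes)
  z <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(nrow(cooc)))
    z[cooc$gene_b[i], cooc$gene_a[i]] <- val[i]
  lim <- max(abs(val), 1)
  .open_device(spec)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(6, 6, 2, 5))
  pal <- grDevices::colorRampPalette(c("purple4", "white", "darkgreen"))(101)
  graphics::image(seq_len(n), seq_len(n), t(z), zlim = c(-lim, lim), col = pal,
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Co-occurrence (green) / mutual exclusivity (purple)")
  graphics::axis(1, at = seq_len(n), labels = genes, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = genes, las = 2, cex.axis = 0.7)
  .write_layout(layout, spec)
}

#' Heat map of driven-cell abundance by mutation status
#'
#' Shows row z-scored abundance of the driven cells with samples grouped
#' mutated | wild-type (all mutated columns first, deterministic sample-id
#' order within group) and a mutation-status annotation bar.
#'
#' @param abundance cells-by-samples matrix.
#' @param mutation_vector named 0/1 vector over the matrix's samples.
#' @param driven_cells non-empty character vector of cell ids to draw.
#' @param spec a [plot_spec()].
#' @return invisibly, the layout table (sample order, group, z values).
#' @export
plot_heatmap_cell <- function(abundance, mutation_vector, driven_cells, spec) {
  .assert_matrix(abundance, "abundance matrix")
  if (!length(driven_cells)) stop("empty driven-cell set", call. = FALSE)
  missing <- setdiff(driven_cells, rownames(abundance))
  if (length(missing)) stop("unknown cell(s): ", paste(missing, collapse = ", "),
                            call. = FALSE)
  if (is.null(names(mutation_vector)))
    names(mutation_vector) <- colnames(abundance)
  mut <- mutation_vector[colnames(abundance)]
  ord <- order(-mut, colnames(abundance))
  z <- zscore_rows(abundance[driven_cells, , drop = FALSE])[, ord, drop = FALSE]
  mut <- mut[ord]
  layout <- data.frame(sample = colnames(z),
                       col = seq_len(ncol(z)),
                       mutated = as.integer(mut),
                       stringsAsFactors = FALSE)
  .open_device(spec)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(4, 8, 3, 2))
  lim <- max(abs(z))
  pal <- grDevices::colorRampPalette(c("navy", "white", "firebrick"))(101)
  graphics::image(seq_len(ncol(z)), seq_len(nrow(z)),
                  t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "samples (mutated | wild-type)", ylab = "")
  graphics::axis(2, at = seq_len(nrow(z)), labels = rev(rownames(z)), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  graphics::abline(v = sum(mut == 1) + 0.5, lwd = 2)
  graphics::mtext(c("mutated", "wild-type"), side = 3, line = 0.2,
                  at = c(sum(mut == 1) / 2, sum(mut == 1) + sum(mut == 0) / 2),
                  cex = 0.8)
  .write_layout(layout, spec)
}

#' Kaplan-Meier curves for risk groups
#'
#' Draws the two group step curves with censoring ticks and annotates the
#' log-rank p-value.
#'
#' @param groups factor of group membership named by sample (e.g. from
#'   [median_split()]).
#' @param survival data frame with `sample`, `time`, `event`.
#' @param spec a [plot_spec()].
#' @return invisibly, the layout table (per-group KM step coordinates).
#' @export
plot_km <- function(groups, survival, spec) {
  lr <- log_rank(groups, survival)
  sv <- survival[match(names(groups), survival$sample), , drop = FALSE]
  g <- factor(groups)
  sf <- survival::survfit(survival::Surv(sv$time, sv$event) ~ g)
  strata_names <- sub("^g=", "", rep(names(sf$strata), sf$strata))
  layout <- data.frame(group = strata_names, time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       n_censor = sf$n.censor, survival = sf$surv,
                       stringsAsFactors = FALSE)
  .open_device(spec)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(sf, col = c("steelblue", "firebrick"), lwd = 2,
                 mark.time = TRUE, xlab = "time", ylab = "survival probability",
                 main = "Kaplan-Meier by risk group")
  graphics::legend("bottomleft", legend = sub("^g=", "", names(sf$strata)),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  graphics::legend("topright", bty = "n",
                   legend = sprintf("log-rank p = %.3g", lr$p))
  .write_layout(layout, spec)
}

#' Plot a fitted risk model's Kaplan-Meier curves
#'
#' @param x a `cell_risk` object.
#' @param spec a [plot_spec()]; required.
#' @param ... unused.
#' @return invisibly, the KM layout table.
#' @export
plot.cell_risk <- function(x, spec, ...) {
  plot_km(x$groups, x$survival, spec)
}
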