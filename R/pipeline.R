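# End-to-end orchestration: expression -> cell abundance -> mutation matrix
# -> driven-cell identification -> risk signatures -> plots, with a
# machine-readable run manifest. All stage parameters live in one config
# object whose defaults are the method's standard settings.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default: 1% mutation-frequency
#' threshold, SAM FDR 0.05, Fisher FDR 0.05, z threshold 2.0, ssGSEA weight
#' alpha 0.25, 1000 permutations, 15-character barcode truncation.
#'
#' @param expression path to a genes-by-samples expression TSV (or `NULL`
#'   when `abundance` is given).
#' @param abundance path to a precomputed cells-by-samples abundance TSV.
#' @param maf path to a MAF file (or `NULL` when `mutation_matrix` is given).
#' @param mutation_matrix path to a precomputed binary mutation matrix TSV.
#' @param gmt path to the cell signature GMT (required with `expression`).
#' @param survival path to the survival TSV, or `NULL` to skip the risk stage.
#' @param out output directory.
#' @param min_freq,sam_fdr,fisher_fdr,z_threshold,alpha,n_perm,seed,barcode_length
#'   stage parameters; see the stage functions.
#' @param min_signature_cells smallest driven-cell set for which a risk
#'   signature is fitted.
#' @return a validated `run_config` list.
#' @export
run_config <- function(expression = NULL, abundance = NULL, maf = NULL,
                       mutation_matrix = NULL, gmt = NULL, survival = NULL,
                       out, min_freq = 0.01, sam_fdr = 0.05,
                       fisher_fdr = 0.05, z_threshold = 2.0, alpha = 0.25,
                       n_perm = 1000L, seed, barcode_length = 15L,
                       min_signature_cells = 2L) {
  if (missing(out)) stop("an output directory is required", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(expression) && is.null(abundance))
    stop("provide an expression matrix or a precomputed abundance matrix",
         call. = FALSE)
  if (!is.null(expression) && is.null(gmt))
    stop("a GMT gene-set file is required to score expression", call. = FALSE)
  if (is.null(maf) && is.null(mutation_matrix))
    stop("provide a MAF file or a precomputed mutation matrix", call. = FALSE)
  stopifnot(min_freq >= 0, min_freq <= 1, sam_fdr > 0, sam_fdr < 1,
            fisher_fdr > 0, fisher_fdr < 1, z_threshold > 0, alpha >= 0,
            n_perm >= 100)
  structure(list(expression = expression, abundance = abundance, maf = maf,
                 mutation_matrix = mutation_matrix, gmt = gmt,
                 survival = survival, out = out, min_freq = min_freq,
                 sam_fdr = sam_fdr, fisher_fdr = fisher_fdr,
                 z_threshold = z_threshold, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 barcode_length = barcode_length,
                 min_signature_cells = as.integer(min_signature_cells)),
            class = "run_config")
}

.stage <- function(name, expr, out_dir) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full identification pipeline
#'
#' Executes, in order: cell-abundance inference (ssGSEA on expression, or
#' import of a precomputed matrix), mutation-matrix construction from MAF,
#' driven-cell identification, pairwise co-occurrence of the hit genes, risk
#' signatures with Kaplan-Meier plots for genes with enough driven cells, a
#' waterfall plot and per-gene heat maps. Writes `summary.tsv`,
#' `details/<gene>.tsv`, plots, and `manifest.json` (configuration, package
#' version, seed, input checksums). Results are deterministic for a fixed
#' seed.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the `cell_assoc` result, any fitted
#'   `cell_risk` models, and the output directory.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "FAILED"))
  say <- function(...) if (!quiet) message(...)

  inputs <- Filter(Negate(is.null),
                   config[c("expression", "abundance", "maf",
                            "mutation_matrix", "gmt", "survival")])
  for (p in inputs)
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)

  say("stage cells: inferring cell abundance")
  ab <- .stage("cells", {
    if (!is.null(config$abundance)) {
      m <- read_expression(config$abundance)
      colnames(m) <- truncate_barcode(colnames(m), config$barcode_length)
      m
    } else {
      expr <- read_expression(config$expression)
      colnames(expr) <- truncate_barcode(colnames(expr), config$barcode_length)
      sets <- read_gmt(config$gmt)
      ssgsea_score(expr, sets, alpha = config$alpha)
    }
  }, out_dir)
  write_matrix(ab, file.path(out_dir, "cell_abundance.tsv"), id_label = "cell")

  say("stage mutmat: building mutation matrix")
  mut <- .stage("mutmat", {
    if (!is.null(config$mutation_matrix)) {
      m <- read_expression(config$mutation_matrix)
      colnames(m) <- truncate_barcode(colnames(m), config$barcode_length)
      .assert_binary(m, "mutation matrix")
      keep <- rowMeans(m) >= config$min_freq
      m <- m[keep, , drop = FALSE]
      m[order(-rowMeans(m), rownames(m)), , drop = FALSE]
    } else {
      maf <- read_maf(config$maf)
      build_mutation_matrix(maf, samples = colnames(ab),
                            min_freq = config$min_freq,
                            barcode_length = config$barcode_length)
    }
  }, out_dir)
  if (!nrow(mut))
    stop("no genes pass the mutation-frequency threshold", call. = FALSE)
  write_matrix(mut, file.path(out_dir, "mutation_matrix.tsv"), id_label = "gene")

  say("stage associate: identifying driven cells for ", nrow(mut), " gene(s)")
  assoc <- .stage("associate",
    find_driven_cells(ab, mut, sam_fdr = config$sam_fdr,
                      fisher_fdr = config$fisher_fdr,
                      z_threshold = config$z_threshold,
                      n_perm = config$n_perm, seed = config$seed),
    out_dir)
  utils::write.table(assoc$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  detail_dir <- file.path(out_dir, "details")
  dir.create(detail_dir, showWarnings = FALSE)
  for (g in names(assoc$genes)) {
    r <- assoc$genes[[g]]
    if (nrow(r))
      utils::write.table(format(r, digits = 15),
                         file.path(detail_dir, paste0(g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    say("  ", g, ": ", sum(r$driven), " driven cell(s)")
  }

  hits <- assoc$summary$gene[assoc$summary$cell_count > 0]
  if (length(hits) >= 2) {
    say("stage cooccur: testing ", length(hits), " hit gene(s)")
    cooc <- .stage("cooccur", cooc_mutex(mut, hits), out_dir)
    utils::write.table(cooc, file.path(out_dir, "cooccurrence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .stage("cooccur_plot",
           plot_cooc_mutex(cooc, plot_spec(file.path(out_dir, "cooc_mutex.pdf"))),
           out_dir)
  }

  .stage("waterfall", {
    genes <- if (length(hits)) hits else rownames(mut)
    plot_waterfall(mut, genes, plot_spec(file.path(out_dir, "waterfall.pdf")))
  }, out_dir)
  for (g in hits) {
    cells <- assoc$genes[[g]]$cell[assoc$genes[[g]]$driven]
    .stage("heatmap",
           plot_heatmap_cell(ab[, assoc$samples, drop = FALSE],
                             mut[g, assoc$samples], cells,
                             plot_spec(file.path(out_dir,
                                                 paste0("heatmap_", g, ".pdf")))),
           out_dir)
  }

  risks <- list()
  if (!is.null(config$survival)) {
    surv <- .stage("survival_read", {
      s <- read_survival(config$survival)
      s$sample <- truncate_barcode(s$sample, config$barcode_length)
      s
    }, out_dir)
    sig_genes <- assoc$summary$gene[assoc$summary$cell_count >=
                                      config$min_signature_cells]
    for (g in sig_genes) {
      say("stage survcell: risk signature for ", g)
      cells <- assoc$genes[[g]]$cell[assoc$genes[[g]]$driven]
      rm_g <- .stage(paste0("survcell_", g),
                     cell_risk_model(ab, cells, surv, gene = g), out_dir)
      risks[[g]] <- rm_g
      utils::write.table(summary(rm_g),
                         file.path(out_dir, paste0("risk_groups_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      plot(rm_g, plot_spec(file.path(out_dir, paste0("km_", g, ".pdf"))))
    }
  }

  manifest <- list(
    package = "mutcell",
    version = as.character(utils::packageVersion("mutcell")),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    n_genes_tested = nrow(mut),
    n_genes_with_driven_cells = length(hits)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  say("done: ", out_dir)
  invisible(list(assoc = assoc, risks = risks, out = out_dir))
}
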