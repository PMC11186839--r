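# Reading cell-level expression matrices and writing result tables, plus
# the end-to-end per-gene pipeline.

#' Read a genes x cells expression matrix with cell metadata
#'
#' Accepts a MatrixMarket (.mtx) sparse matrix (1-based indices per the
#' MatrixMarket standard) or a dense TSV with genes in rows, together with
#' a TSV metadata table holding columns `cell_id`, `individual`,
#' `cell_type` (one row per cell, in matrix column order or keyed by a
#' `genes`/`cells` sidecar). Expression is assumed pre-normalized and
#' log-transformed.
#'
#' @param matrix_path path to the .mtx or dense .tsv expression matrix.
#' @param cells_path path to the cell metadata TSV.
#' @param genes_path optional path to a one-column file of gene names
#'   (required for MTX input).
#' @return list with `expr` (genes x cells matrix, possibly sparse),
#'   `cells` (metadata data.frame), `genes` (character vector).
#' @export
read_cell_matrix <- function(matrix_path, cells_path, genes_path = NULL) {
  meta <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "individual", "cell_type")
  if (!all(need %in% names(meta)))
    stop("cell metadata must have columns: ", paste(need, collapse = ", "),
         " (file ", cells_path, ")")
  if (grepl("\\.mtx$", matrix_path)) {
    expr <- Matrix::readMM(matrix_path)
    if (is.null(genes_path))
      stop("MTX input requires a gene-name file (genes_path)")
    genes <- readLines(genes_path)
    if (length(genes) != nrow(expr))
      stop(sprintf("gene file has %d names but matrix has %d rows (%s)",
                   length(genes), nrow(expr), matrix_path))
  } else {
    tab <- utils::read.delim(matrix_path, row.names = 1, check.names = FALSE)
    expr <- as.matrix(tab)
    genes <- rownames(expr)
  }
  if (ncol(expr) != nrow(meta))
    stop(sprintf("matrix has %d cells but metadata has %d rows (%s vs %s)",
                 ncol(expr), nrow(meta), matrix_path, cells_path))
  list(expr = expr, cells = meta, genes = genes)
}

#' Extract one gene as a [cell_gene]
#'
#' @param data result of [read_cell_matrix()].
#' @param gene gene name or row index.
#' @return A `cell_gene`.
#' @export
gene_cells <- function(data, gene) {
  i <- if (is.character(gene)) match(gene, data$genes) else gene
  if (is.na(i) || i < 1 || i > length(data$genes))
    stop("unknown gene: ", gene)
  cell_gene(as.numeric(data$expr[i, ]), data$cells$individual,
            data$cells$cell_type, gene = data$genes[i])
}

#' Write per-gene pseudobulk tables
#'
#' Serializes a pseudobulk bundle as TSV tables (y, nu, n, P) with
#' individual row labels and cell-type column labels.
#'
#' @param pb a `pseudobulk`.
#' @param dir output directory; files are named `<prefix>_<table>.tsv`.
#' @param prefix file-name prefix (default the gene name).
#' @return invisibly, the written paths.
#' @export
write_pseudobulk <- function(pb, dir, prefix = NULL) {
  if (is.null(prefix)) prefix <- if (!is.null(pb$gene)) pb$gene else "gene"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tab in c("y", "nu", "n", "P")) {
    path <- file.path(dir, paste0(prefix, "_", tab, ".tsv"))
    utils::write.table(pb[[tab]], path, sep = "\t", quote = FALSE,
                       col.names = NA)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Run the per-gene analysis pipeline
#'
#' For each gene: aggregate cells into pseudobulk, apply the cell-count
#' missingness rules, standardize to the OP scale, impute missing entries
#' (low-rank completion of y; nu imputed likewise and repaired to be
#' nonnegative), fit the Hom and Free models, test for cell type-specific
#' variance and for mean differentiation, and apply Bonferroni correction
#' across genes.
#'
#' @param data result of [read_cell_matrix()], or a named list of
#'   [cell_gene] objects.
#' @param mode "CTP" or "OP".
#' @param estimator "reml", "ml" or "he".
#' @param variance_test "lrt", "wald_jackknife" or "wald_fisher" (HE fits
#'   always use the jackknife Wald).
#' @param covariates optional individual-level covariate matrix with
#'   rownames matching individual labels.
#' @param batch optional named batch assignment (names = individuals).
#' @param min_cells,min_cells_per_individual missingness thresholds.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param seed RNG seed (restarts, imputation folds).
#' @param mean_test also run the mean-differentiation test (needs the
#'   jackknife; slower).
#' @return data.frame with one row per gene: estimates, p-values,
#'   convergence flags, Bonferroni significance.
#' @export
run_pipeline <- function(data, mode = c("CTP", "OP"), estimator = "reml",
                         variance_test = "lrt", covariates = NULL,
                         batch = NULL, min_cells = 10,
                         min_cells_per_individual = 100, alpha = 0.05,
                         seed = 1L, mean_test = FALSE) {
  mode <- match.arg(mode)
  set.seed(seed)
  gene_list <- if (!is.null(data$expr)) {
    stats::setNames(lapply(seq_along(data$genes), function(i)
      gene_cells(data, i)), data$genes)
  } else data
  rows <- list()
  for (g in names(gene_list)) {
    row <- tryCatch(
      pipeline_one_gene(gene_list[[g]], mode, estimator, variance_test,
                        covariates, batch, min_cells,
                        min_cells_per_individual, mean_test),
      error = function(e) {
        data.frame(gene = g, method = estimator, converged = FALSE,
                   p_variance = NA_real_, p_mean = NA_real_,
                   sigma_alpha2 = NA_real_, error = conditionMessage(e))
      })
    row$gene <- g
    rows[[g]] <- row
  }
  res <- do.call(rbind, lapply(rows, pad_row,
                               cols = Reduce(union, lapply(rows, names))))
  rownames(res) <- NULL
  bf <- bonferroni(res$p_variance, alpha)
  res$significant_variance <- bf$significant
  attr(res, "bonferroni_threshold") <- bf$threshold
  attr(res, "seed") <- seed
  attr(res, "package_version") <- as.character(utils::packageVersion("ctvmm"))
  res
}

pad_row <- function(row, cols) {
  for (cc in setdiff(cols, names(row))) row[[cc]] <- NA
  row[cols]
}

pipeline_one_gene <- function(cells, mode, estimator, variance_test,
                              covariates, batch, min_cells,
                              min_cells_per_individual, mean_test) {
  pb <- aggregate_cells(cells)
  pb <- apply_missingness(pb, min_cells, min_cells_per_individual)
  pb <- standardize_pseudobulk(pb)
  if (any(pb$mask)) {
    raw_nu <- pb$nu
    pb$y <- impute_lowrank(pb$y)
    pb$nu <- repair_negative_nu(impute_lowrank(pb$nu), mode = "CTP",
                                raw_nu = raw_nu)
    pb$y_op <- rowSums(pb$P * pb$y)
    pb$nu_op <- rowSums(pb$P^2 * pb$nu)
  }
  cov_m <- if (!is.null(covariates))
    covariates[pb$individuals, , drop = FALSE] else NULL
  bat <- if (!is.null(batch)) factor(batch[pb$individuals]) else NULL
  spec_free <- ctmm_spec("free", mode, covariates = cov_m, batch = bat)
  spec_hom <- ctmm_spec("hom", mode, covariates = cov_m, batch = bat)
  if (estimator == "he") {
    ff <- fit_he(pb, spec_free)
    fh <- NULL
  } else {
    ff <- fit_likelihood(pb, spec_free, estimator)
    fh <- fit_likelihood(pb, spec_hom, estimator)
  }
  conv <- ff$converged && (is.null(fh) || fh$converged)
  out <- data.frame(gene = NA_character_, method = estimator,
                    converged = conv,
                    p_variance = NA_real_, p_mean = NA_real_,
                    sigma_alpha2 = ff$params$sigma_alpha2)
  for (cc in seq_len(ff$C)) out[[paste0("V_", cc)]] <- diag(ff$params$V)[cc]
  if (!conv) return(out)
  jk <- NULL
  if (estimator == "he" || variance_test == "wald_jackknife" || mean_test)
    jk <- jackknife_fit(pb, ff)
  out$p_variance <-
    if (estimator == "he" || variance_test == "wald_jackknife")
      wald_variance_test(ff, pb, "jackknife", jack = jk)$p_value
    else if (variance_test == "wald_fisher")
      wald_variance_test(ff, pb, "fisher")$p_value
    else lrt_free_vs_hom(ff, fh)$p_value
  if (mean_test)
    out$p_mean <- mean_differentiation_test(pb, ff, jack = jk)$p_value
  out
}

#' Write a results table as TSV
#'
#' @param results data.frame from [run_pipeline()] or
#'   [operating_characteristics()].
#' @param path output path.
#' @export
write_results <- function(results, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
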