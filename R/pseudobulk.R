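#' Cell-level expression for one gene
#'
#' Bundles the per-cell expression values of a single gene with the
#' individual (donor) and cell-type label of every cell. Expression is
#' assumed already library-normalized and log-transformed; no further
#' normalization is performed.
#'
#' @param values numeric vector of per-cell expression values.
#' @param individual character/factor vector of donor labels, one per cell.
#' @param cell_type character/factor vector of cell-type labels, one per cell.
#' @param gene optional gene name.
#' @return An object of class `cell_gene`.
#' @export
cell_gene <- function(values, individual, cell_type, gene = NULL) {
  if (length(values) == 0L) stop("empty gene: no cells supplied")
  if (length(individual) != length(values) || length(cell_type) != length(values))
    stop("values, individual and cell_type must have equal length")
  if (anyNA(values) || anyNA(individual) || anyNA(cell_type))
    stop("missing values are not allowed in cell-level input")
  structure(
    list(values = as.numeric(values),
         individual = as.character(individual),
         cell_type = as.character(cell_type),
         gene = gene),
    class = "cell_gene")
}

#' @export
print.cell_gene <- function(x, ...) {
  cat("<cell_gene>", if (!is.null(x$gene)) x$gene else "",
      sprintf("- %d cells, %d individuals, %d cell types\n",
              length(x$values), length(unique(x$individual)),
              length(unique(x$cell_type))))
  invisible(x)
}

new_pseudobulk <- function(y, nu, n, individuals, cell_types, gene = NULL,
                           scale_record = NULL) {
  dimnames(y) <- dimnames(nu) <- dimnames(n) <-
    list(individuals, cell_types)
  n_i <- rowSums(n)
  P <- n / n_i
  # OP summaries: nu_op = sum_c n_ic / n_i^2 * sigma2_ic = sum_c P_ic^2 nu_ic
  y_op <- rowSums(P * y)
  nu_op <- rowSums(P^2 * nu)
  structure(
    list(y = y, nu = nu, n = n, P = P,
         y_op = y_op, nu_op = nu_op,
         mask = is.na(y),
         individuals = individuals, cell_types = cell_types,
         gene = gene, scale_record = scale_record),
    class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk>%s %d individuals x %d cell types (%d missing entries)\n",
              if (!is.null(x$gene)) paste0(" ", x$gene) else "",
              nrow(x$y), ncol(x$y), sum(x$mask)))
  invisible(x)
}

#' @export
dim.pseudobulk <- function(x) dim(x$y)

#' Aggregate cell-level expression into pseudobulk summaries
#'
#' Computes, for each individual i and cell type c, the cell type-specific
#' pseudobulk mean `y[i,c]` (the average expression over that pair's cells)
#' and its noise variance `nu[i,c] = sigma2_ic / n_ic`, where `sigma2_ic` is
#' the unbiased sample variance across cells within the pair. The overall
#' pseudobulk `y_op[i]` averages over all of an individual's cells, with
#' noise variance `nu_op[i] = sum_c (n_ic / n_i^2) * sigma2_ic`, and
#' `P[i,c] = n_ic / n_i` records cell-type proportions.
#'
#' Pairs with a single cell have an undefined sample variance and are set
#' missing. Pairs with zero cells are missing by construction.
#'
#' @param cells a [cell_gene] object.
#' @param keep_largest_replicate if an individual label contains a replicate
#'   suffix separated by `replicate_sep`, keep only the replicate with the
#'   most cells for each base individual.
#' @param replicate_sep separator between individual id and replicate id.
#' @return A `pseudobulk` object.
#' @export
aggregate_cells <- function(cells, keep_largest_replicate = FALSE,
                            replicate_sep = ":") {
  stopifnot(inherits(cells, "cell_gene"))
  individual <- cells$individual
  if (keep_largest_replicate) {
    base <- sub(paste0(replicate_sep, ".*$"), "", individual)
    cnt <- table(individual)
    # per base individual, the replicate label with the most cells
    keep <- tapply(names(cnt), sub(paste0(replicate_sep, ".*$"), "", names(cnt)),
                   function(labs) labs[which.max(cnt[labs])])
    sel <- individual %in% unlist(keep)
    cells <- cell_gene(cells$values[sel], base[sel], cells$cell_type[sel],
                       gene = cells$gene)
    individual <- cells$individual
  }
  ind <- factor(individual)
  ct <- factor(cells$cell_type)
  N <- nlevels(ind); C <- nlevels(ct)
  idx <- (as.integer(ind) - 1L) * C + as.integer(ct)
  n_vec <- tabulate(idx, nbins = N * C)
  sum_vec <- rep(0, N * C)
  sumsq_vec <- rep(0, N * C)
  agg <- rowsum(cbind(cells$values, cells$values^2), idx)
  at <- as.integer(rownames(agg))
  sum_vec[at] <- agg[, 1]; sumsq_vec[at] <- agg[, 2]
  ybar <- ifelse(n_vec > 0, sum_vec / n_vec, NA_real_)
  s2 <- ifelse(n_vec > 1, (sumsq_vec - n_vec * ybar^2) / (n_vec - 1), NA_real_)
  s2[n_vec > 1 & s2 < 0] <- 0  # guard tiny negative rounding
  nu <- s2 / n_vec
  ybar[n_vec <= 1] <- NA_real_  # single-cell pairs: variance undefined
  nu[n_vec <= 1] <- NA_real_
  y_mat <- matrix(ybar, N, C, byrow = TRUE)
  nu_mat <- matrix(nu, N, C, byrow = TRUE)
  n_mat <- matrix(n_vec, N, C, byrow = TRUE)
  new_pseudobulk(y_mat, nu_mat, n_mat, levels(ind), levels(ct),
                 gene = cells$gene)
}

#' Apply cell-count missingness rules to a pseudobulk object
#'
#' Entries backed by no more than `min_cells` cells are set missing (both
#' the pseudobulk mean and its noise variance): with few cells the Gaussian
#' approximation for the pair's noise is unreliable. Individuals with fewer
#' than `min_cells_per_individual` cells in total are dropped entirely.
#'
#' @param pb a `pseudobulk` object.
#' @param min_cells entries with `n[i,c] <= min_cells` become missing
#'   (default 10; 5 and 20 are reasonable robustness settings).
#' @param min_cells_per_individual individuals with fewer total cells are
#'   removed (default 100).
#' @return The filtered `pseudobulk` object.
#' @export
apply_missingness <- function(pb, min_cells = 10, min_cells_per_individual = 100) {
  stopifnot(inherits(pb, "pseudobulk"))
  keep <- rowSums(pb$n) >= min_cells_per_individual
  if (!any(keep)) stop("all individuals removed by the per-individual cell filter")
  y <- pb$y[keep, , drop = FALSE]
  nu <- pb$nu[keep, , drop = FALSE]
  n <- pb$n[keep, , drop = FALSE]
  drop_entry <- n <= min_cells
  y[drop_entry] <- NA_real_
  nu[drop_entry] <- NA_real_
  if (all(is.na(y))) stop("all pseudobulk entries missing after filtering")
  new_pseudobulk(y, nu, n, pb$individuals[keep], pb$cell_types,
                 gene = pb$gene, scale_record = pb$scale_record)
}

#' Standardize pseudobulk to the overall-pseudobulk scale
#'
#' Centers and scales so the overall pseudobulk (OP) has mean 0 and
#' variance 1 (sample, n-1 convention). CTP entries are shifted by the OP
#' mean and divided by the OP standard deviation; noise variances are
#' divided by the OP variance. The transformation is recorded in
#' `$scale_record` and can be undone with [unstandardize_pseudobulk()].
#'
#' @param pb a `pseudobulk` object with at least two individuals.
#' @return The standardized `pseudobulk`.
#' @export
standardize_pseudobulk <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk"))
  y_op <- complete_op(pb)
  if (length(y_op) < 2) stop("need at least two individuals to standardize")
  mu <- mean(y_op)
  v <- stats::var(y_op)
  if (!is.finite(v) || v <= 0) stop("constant OP vector: cannot standardize")
  s <- sqrt(v)
  out <- new_pseudobulk((pb$y - mu) / s, pb$nu / v, pb$n,
                        pb$individuals, pb$cell_types, gene = pb$gene,
                        scale_record = list(center = mu, scale = s))
  out
}

#' Invert a recorded standardization
#'
#' @param pb a standardized `pseudobulk` with a `$scale_record`.
#' @return The `pseudobulk` on its original scale.
#' @export
unstandardize_pseudobulk <- function(pb) {
  sr <- pb$scale_record
  if (is.null(sr)) stop("no scale record: pseudobulk is not standardized")
  new_pseudobulk(pb$y * sr$scale + sr$center, pb$nu * sr$scale^2, pb$n,
                 pb$individuals, pb$cell_types, gene = pb$gene)
}

# OP vector where every cell type is observed; rows with missing entries use
# the observed-cell average (the raw per-individual mean over all cells).
complete_op <- function(pb) {
  pb$y_op[is.finite(pb$y_op)]
}

#' Construct a pseudobulk object from precomputed matrices
#'
#' For data already summarized (e.g., simulated directly at the pseudobulk
#' level), builds a `pseudobulk` without cell-level input.
#'
#' @param y N x C matrix of CTP means (NA = missing).
#' @param nu N x C matrix of noise variances.
#' @param P optional N x C proportion matrix (default equal proportions).
#' @param n optional N x C cell-count matrix.
#' @param gene optional gene name.
#' @return A `pseudobulk` object.
#' @export
as_pseudobulk <- function(y, nu, P = NULL, n = NULL, gene = NULL) {
  y <- as.matrix(y); nu <- as.matrix(nu)
  stopifnot(all(dim(y) == dim(nu)))
  N <- nrow(y); C <- ncol(y)
  if (is.null(P)) P <- matrix(1 / C, N, C)
  if (is.null(n)) n <- matrix(100L, N, C)
  ind <- rownames(y); if (is.null(ind)) ind <- paste0("i", seq_len(N))
  cts <- colnames(y); if (is.null(cts)) cts <- paste0("ct", seq_len(C))
  pb <- new_pseudobulk(y, nu, n, ind, cts, gene = gene)
  pb$P <- P; dimnames(pb$P) <- list(ind, cts)
  pb$y_op <- rowSums(P * y)
  pb$nu_op <- rowSums(P^2 * nu)
  pb
}
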