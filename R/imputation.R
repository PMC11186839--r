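# Imputation of structured-missing pseudobulk entries. Missingness arises
# from the cell-count filter: when an individual has too few cells of a
# cell type, that entire (individual, cell type) entry is missing for every
# gene. Two per-gene imputers are provided (iterative soft-thresholded SVD
# and an EM-fitted multivariate normal) plus a transcriptome-wide low-rank
# imputer on the N x (C*G) stacked matrix, and the copy-mask benchmarking
# scheme.

#' Low-rank (soft-thresholded SVD) matrix completion
#'
#' Iteratively fills missing entries with the current low-rank
#' reconstruction: at each step the completed matrix is decomposed by SVD,
#' singular values are soft-thresholded by `lambda`, and the missing
#' entries are replaced by the reconstruction. Observed entries are never
#' altered.
#'
#' @param x numeric matrix with NAs at missing entries.
#' @param lambda soft-threshold on the singular values; `NULL` selects
#'   lambda by 5-fold entry-held-out cross-validation over `lambda_grid`.
#' @param lambda_grid candidate thresholds as fractions of the largest
#'   singular value of the mean-filled matrix.
#' @param rank maximum reconstruction rank (singular values beyond it are
#'   dropped); default one less than the smaller matrix dimension, so a
#'   small `lambda` still forces a low-rank reconstruction.
#' @param max_iter,tol iteration controls.
#' @param seed RNG seed for the cross-validation folds.
#' @return The completed matrix.
#' @export
impute_lowrank <- function(x, lambda = NULL,
                           lambda_grid = c(0.02, 0.05, 0.1, 0.2, 0.4),
                           rank = NULL, max_iter = 200, tol = 1e-6,
                           seed = 1L) {
  x <- as.matrix(x)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (any(colSums(!miss) < 2))
    stop("each column needs at least 2 observed entries")
  if (is.null(rank)) rank <- max(1L, min(dim(x)) - 1L)
  if (is.null(lambda)) {
    lambda <- cv_lambda(x, lambda_grid, rank = rank, seed = seed)
  }
  soft_impute_fixed(x, lambda, rank, max_iter, tol)
}

soft_impute_fixed <- function(x, lambda, rank = max(1L, min(dim(x)) - 1L),
                              max_iter = 200, tol = 1e-6) {
  miss <- is.na(x)
  cm <- colMeans(x, na.rm = TRUE)
  filled <- x
  filled[miss] <- matrix(cm, nrow(x), ncol(x), byrow = TRUE)[miss]
  for (it in seq_len(max_iter)) {
    sv <- svd(filled)
    d <- pmax(sv$d - lambda, 0)
    if (length(d) > rank) d[-seq_len(rank)] <- 0
    recon <- sv$u %*% (d * t(sv$v))
    new <- x
    new[miss] <- recon[miss]
    delta <- sqrt(mean((new[miss] - filled[miss])^2))
    filled <- new
    if (delta < tol) break
  }
  filled
}

cv_lambda <- function(x, grid, rank, n_folds = 5, seed = 1L) {
  obs <- which(!is.na(x))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), length(obs)))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  d1 <- svd(soft_impute_fixed(x, 0, max_iter = 1))$d[1]
  errs <- sapply(grid, function(g) {
    lam <- g * d1
    err <- 0
    for (f in seq_len(n_folds)) {
      xh <- x
      held <- obs[fold == f]
      xh[held] <- NA
      if (any(colSums(!is.na(xh)) < 2)) return(Inf)
      fit <- soft_impute_fixed(xh, lam)
      err <- err + sum((fit[held] - x[held])^2)
    }
    err
  })
  grid[which.min(errs)] * d1
}

#' Multivariate-normal (EM) imputation of one gene
#'
#' Treats the rows (individuals) as i.i.d. draws from a C-variate Gaussian,
#' fits the mean and covariance by EM over the missing entries, and
#' replaces each missing entry by its conditional mean given the observed
#' entries in the same row. Observed entries are never altered.
#'
#' @param x N x C matrix with NAs.
#' @param max_iter,tol EM controls.
#' @param ridge small diagonal inflation keeping the working covariance
#'   invertible.
#' @return The completed matrix, with attribute `converged`.
#' @export
impute_mvn <- function(x, max_iter = 200, tol = 1e-8, ridge = 1e-8) {
  x <- as.matrix(x)
  miss <- is.na(x)
  if (!any(miss)) return(structure(x, converged = TRUE))
  N <- nrow(x); C <- ncol(x)
  mu <- colMeans(x, na.rm = TRUE)
  filled <- x
  filled[miss] <- matrix(mu, N, C, byrow = TRUE)[miss]
  Sg <- stats::cov(filled) + diag(ridge, C)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step: conditional means, and conditional covariance contribution
    Ssum <- matrix(0, C, C)
    for (i in seq_len(N)) {
      m <- miss[i, ]
      if (!any(m)) next
      o <- !m
      if (any(o)) {
        Soo <- Sg[o, o, drop = FALSE]
        Smo <- Sg[m, o, drop = FALSE]
        sol <- Smo %*% solve(Soo)
        filled[i, m] <- mu[m] + drop(sol %*% (x[i, o] - mu[o]))
        Cc <- Sg[m, m, drop = FALSE] - sol %*% t(Smo)
      } else {
        filled[i, m] <- mu[m]
        Cc <- Sg[m, m, drop = FALSE]
      }
      Si <- matrix(0, C, C)
      Si[m, m] <- Cc
      Ssum <- Ssum + Si
    }
    mu_new <- colMeans(filled)
    ctr <- sweep(filled, 2, mu_new)
    Sg_new <- (crossprod(ctr) + Ssum) / N + diag(ridge, C)
    delta <- max(abs(mu_new - mu), abs(Sg_new - Sg))
    mu <- mu_new; Sg <- Sg_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(filled, converged = converged)
}

#' Transcriptome-wide low-rank imputation
#'
#' Applies the soft-thresholded SVD completion jointly to all genes by
#' stacking their N x C matrices horizontally into an N x (C*G) matrix,
#' borrowing strength across genes through shared individual-level factors.
#' With a single gene this reduces exactly to [impute_lowrank()].
#'
#' @param mats list of N x C matrices (one per gene), or a prestacked
#'   N x (C*G) matrix.
#' @inheritParams impute_lowrank
#' @return A list of completed matrices (or a completed matrix if a matrix
#'   was supplied).
#' @export
impute_transcriptomewide_lowrank <- function(mats, lambda = NULL,
                                             lambda_grid = c(0.02, 0.05, 0.1, 0.2, 0.4),
                                             rank = NULL, max_iter = 200,
                                             tol = 1e-6, seed = 1L) {
  single <- is.matrix(mats)
  if (single) mats <- list(mats)
  Cs <- vapply(mats, ncol, 1L)
  stack <- do.call(cbind, mats)
  done <- impute_lowrank(stack, lambda = lambda, lambda_grid = lambda_grid,
                         rank = rank, max_iter = max_iter, tol = tol,
                         seed = seed)
  out <- vector("list", length(mats))
  at <- 0L
  for (g in seq_along(mats)) {
    out[[g]] <- done[, (at + 1L):(at + Cs[g]), drop = FALSE]
    dimnames(out[[g]]) <- dimnames(mats[[g]])
    at <- at + Cs[g]
  }
  if (single) out[[1]] else out
}

#' Repair negative imputed noise variances
#'
#' Imputation can produce negative noise variances. In OP mode these are
#' clamped to 0 (so they contribute nothing to nu_i while keeping the other
#' cell types' information); in CTP mode each negative entry is replaced by
#' the maximum observed raw nu in that gene and cell type, downweighting
#' the entry in the likelihood.
#'
#' @param nu_imputed N x C matrix of imputed noise variances.
#' @param mode "OP" or "CTP".
#' @param raw_nu the pre-imputation N x C nu matrix (with NAs); required
#'   for CTP mode.
#' @return The repaired, everywhere-nonnegative nu matrix.
#' @export
repair_negative_nu <- function(nu_imputed, mode = c("OP", "CTP"),
                               raw_nu = NULL) {
  mode <- match.arg(mode)
  out <- as.matrix(nu_imputed)
  neg <- which(out < 0, arr.ind = TRUE)
  if (nrow(neg) == 0) return(out)
  if (mode == "OP") {
    out[out < 0] <- 0
    return(out)
  }
  if (is.null(raw_nu)) stop("CTP mode requires the raw (pre-imputation) nu")
  cmax <- apply(as.matrix(raw_nu), 2, function(z)
    if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE))
  for (k in seq_len(nrow(neg))) {
    cc <- neg[k, 2]
    if (is.na(cmax[cc]))
      stop(sprintf("no observed raw nu in cell type %d: cannot repair", cc))
    out[neg[k, 1], cc] <- cmax[cc]
  }
  out
}

#' Build a copy-mask plan
#'
#' Copies the missingness pattern of randomly chosen donor individuals
#' (their set of missing cell types) onto randomly chosen recipients, entire
#' cell types at a time, until at least `fraction` of all (individual, cell
#' type) pairs are masked. The donor pool is the set of individuals that
#' already have missing cell types, so the synthetic missingness mirrors
#' the structure of the real missingness.
#'
#' @param mask N x C logical matrix of real missingness.
#' @param fraction target masked proportion of all pairs (default 0.10).
#' @param replicate_id replicate number (combined with `seed` for the RNG).
#' @param seed base seed; the replicate uses `seed + replicate_id`.
#' @return list with `masked` (N x C logical: newly masked entries),
#'   `fraction`, `replicate_id`.
#' @export
mask_plan <- function(mask, fraction = 0.10, replicate_id = 1L, seed = 1L) {
  mask <- as.matrix(mask)
  N <- nrow(mask); C <- ncol(mask)
  donors <- which(rowSums(mask) > 0)
  if (length(donors) == 0)
    stop("no individual with missing cell types to donate a pattern")
  set.seed(seed + as.integer(replicate_id))
  new_mask <- matrix(FALSE, N, C)
  target <- ceiling(fraction * N * C)
  # recipients are fully observed individuals; each receives one donor's
  # complete missing pattern, so every masked recipient's missing set
  # equals some donor's
  pool <- which(rowSums(mask) == 0)
  pool <- pool[sample.int(length(pool))]
  for (r in pool) {
    if (sum(new_mask) >= target) break
    d <- donors[sample.int(length(donors), 1)]
    new_mask[r, mask[d, ]] <- TRUE
  }
  if (sum(new_mask) < target)
    warning("ran out of fully observed recipients before reaching the ",
            "target masked fraction")
  list(masked = new_mask, fraction = fraction, replicate_id = replicate_id)
}

#' Benchmark imputation accuracy by copy-masking
#'
#' For each replicate, masks ~10% of observed (individual, cell type)
#' pairs with [mask_plan()], imputes each gene with `imputer`, and scores
#' the imputed against the held-out true values per gene and cell type.
#' Reports the median correlation and median MSE over replicates.
#'
#' @param mats list of per-gene N x C matrices (with any real NAs).
#' @param imputer function taking one N x C matrix with NAs and returning
#'   the completed matrix, or the string "transcriptomewide" to impute all
#'   genes jointly with [impute_transcriptomewide_lowrank()].
#' @param n_replicates number of mask/impute replicates (default 10).
#' @param fraction target masked fraction.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return data.frame: gene, cell_type, median_correlation, median_mse,
#'   n_replicates. Pairs with fewer than 2 masked values in a replicate get
#'   NA correlation for that replicate.
#' @export
copy_mask_evaluate <- function(mats, imputer, n_replicates = 10,
                               fraction = 0.10, seed = 1L) {
  G <- length(mats)
  N <- nrow(mats[[1]]); C <- ncol(mats[[1]])
  base_mask <- is.na(mats[[1]])
  cors <- array(NA_real_, c(G, C, n_replicates))
  mses <- array(NA_real_, c(G, C, n_replicates))
  joint <- identical(imputer, "transcriptomewide")
  for (r in seq_len(n_replicates)) {
    plan <- mask_plan(base_mask, fraction, replicate_id = r, seed = seed)
    masked_mats <- lapply(mats, function(m) { m[plan$masked] <- NA; m })
    imputed <- if (joint) impute_transcriptomewide_lowrank(masked_mats)
               else lapply(masked_mats, imputer)
    for (g in seq_len(G)) for (cc in seq_len(C)) {
      sel <- plan$masked[, cc] & !base_mask[, cc]
      if (!any(sel)) next
      truth <- mats[[g]][sel, cc]
      est <- imputed[[g]][sel, cc]
      mses[g, cc, r] <- mean((est - truth)^2)
      if (sum(sel) >= 2 && stats::sd(truth) > 0 && stats::sd(est) > 0)
        cors[g, cc, r] <- stats::cor(truth, est)
    }
  }
  out <- expand.grid(gene = seq_len(G), cell_type = seq_len(C))
  out$median_correlation <- mapply(function(g, cc)
    stats::median(cors[g, cc, ], na.rm = TRUE), out$gene, out$cell_type)
  out$median_mse <- mapply(function(g, cc)
    stats::median(mses[g, cc, ], na.rm = TRUE), out$gene, out$cell_type)
  out$n_replicates <- n_replicates
  out
}
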