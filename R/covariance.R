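#' Model specification for a cell type-specific mixed model
#'
#' Chooses the covariance structure of the cell type-specific random effect
#' V, the data mode, and the fixed/random-effect designs.
#'
#' Structures:
#' * `hom`:  V = 0 — all interindividual variance shared across cell types.
#' * `iid`:  V = v I — equal cell type-specific variance in every cell type.
#' * `free`: V diagonal — independent per-cell-type variances.
#' * `full`: V an arbitrary symmetric matrix; `sigma_alpha2` is fixed at 0
#'   because passing a constant between `sigma_alpha2` and V (adding
#'   lambda * J to V) leaves the likelihood unchanged.
#'
#' @param structure one of "hom", "iid", "free", "full".
#' @param mode "CTP" (cell type-specific pseudobulk, the N x C layout) or
#'   "OP" (overall pseudobulk, one value per individual).
#' @param covariates optional N x K matrix of individual-level covariates
#'   (fixed effects beyond the cell-type intercepts).
#' @param batch optional length-N factor assigning individuals to blocks
#'   (e.g., experimental batch) modeled as an extra random effect.
#' @return An object of class `ctmm_spec`.
#' @export
ctmm_spec <- function(structure = c("free", "hom", "iid", "full"),
                      mode = c("CTP", "OP"),
                      covariates = NULL, batch = NULL) {
  structure <- match.arg(structure)
  mode <- match.arg(mode)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  if (!is.null(batch)) batch <- factor(batch)
  structure(list(structure = structure, mode = mode,
                 covariates = covariates, batch = batch),
            class = "ctmm_spec")
}

#' @export
print.ctmm_spec <- function(x, ...) {
  cat(sprintf("<ctmm_spec> %s / %s%s%s\n", x$structure, x$mode,
              if (!is.null(x$covariates))
                sprintf(", %d covariates", ncol(x$covariates)) else "",
              if (!is.null(x$batch))
                sprintf(", %d batches", nlevels(x$batch)) else ""))
  invisible(x)
}

# Number of model parameters per structure (Free-model R = 2C+1 is the count
# used in all Wald denominator degrees of freedom).
n_params <- function(structure, C) {
  switch(structure,
         hom  = C + 1,
         iid  = C + 2,
         free = 2 * C + 1,
         full = C + C * (C + 1) / 2,
         stop("unknown structure"))
}

#' Variance-component parameter bundle
#'
#' @param beta cell-type fixed effects (length C), plus covariate
#'   coefficients appended if present.
#' @param sigma_alpha2 shared (homogeneous) interindividual variance.
#' @param V C x C symmetric cell type-specific (co)variance matrix.
#' @param batch_var variance of the blocked random effect (0 if absent).
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(beta, sigma_alpha2, V, batch_var = 0) {
  V <- as.matrix(V)
  if (!isSymmetric(unname(V), tol = 1e-8)) stop("V must be symmetric")
  structure(list(beta = beta, sigma_alpha2 = sigma_alpha2, V = V,
                 batch_var = batch_var),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components>\n")
  cat("  sigma_alpha2:", format(x$sigma_alpha2, digits = 4), "\n")
  cat("  diag(V):     ", paste(format(diag(x$V), digits = 4), collapse = " "), "\n")
  if (x$batch_var != 0) cat("  batch_var:   ", format(x$batch_var, digits = 4), "\n")
  invisible(x)
}

# ---- design matrices ------------------------------------------------------

# CTP observations are stacked individual-major: row (i-1)*C + c.
ctp_design <- function(N, C, covariates = NULL) {
  X <- kronecker(rep(1, N), diag(C))
  if (!is.null(covariates)) {
    X <- cbind(X, covariates[rep(seq_len(N), each = C), , drop = FALSE])
  }
  X
}

op_design <- function(P, covariates = NULL) {
  X <- P
  if (!is.null(covariates)) X <- cbind(X, covariates)
  X
}

# Batch indicator on the observation scale.
batch_Z <- function(batch, per = c("ctp", "op"), C = 1L) {
  per <- match.arg(per)
  Zi <- stats::model.matrix(~ 0 + batch)
  if (per == "ctp") Zi <- Zi[rep(seq_len(nrow(Zi)), each = C), , drop = FALSE]
  unname(Zi)
}

# ---- dense covariance construction (oracle path) --------------------------

#' Dense CTP covariance matrix and mean
#'
#' Naive construction of the NC x NC covariance implied by the model: each
#' individual contributes a C x C block `sigma_alpha2 * J + V + diag(nu_i.)`,
#' blocks are independent across individuals, and a blocked random effect
#' adds `batch_var` to every pair of observations sharing a batch. Used as
#' the reference the fast block-structured likelihood is validated against.
#'
#' @param spec a [ctmm_spec] with mode "CTP".
#' @param params a [variance_components].
#' @param pb a complete `pseudobulk` object.
#' @return list with `Sigma` (NC x NC), `mean` (length NC), `X` (design).
#' @export
ctp_covariance <- function(spec, params, pb) {
  stopifnot(spec$mode == "CTP")
  if (anyNA(pb$y)) stop("missing pseudobulk entries: impute before modeling")
  N <- nrow(pb$y); C <- ncol(pb$y)
  Vfull <- expand_V(spec$structure, params, C)
  blocks <- lapply(seq_len(N), function(i)
    params$sigma_alpha2 + Vfull + diag(pb$nu[i, ], C))
  Sigma <- as.matrix(Matrix::bdiag(blocks))
  if (!is.null(spec$batch)) {
    Z <- batch_Z(spec$batch, "ctp", C)
    Sigma <- Sigma + params$batch_var * tcrossprod(Z)
  }
  check_pd(Sigma, params)
  X <- ctp_design(N, C, spec$covariates)
  list(Sigma = Sigma, mean = drop(X %*% params$beta), X = X)
}

#' Dense OP covariance matrix and mean
#'
#' `var(y_i) = sigma_alpha2 + P_i' V P_i + nu_i`; mean is
#' `sum_c P_ic beta_c` plus covariate terms.
#'
#' @inheritParams ctp_covariance
#' @return list with `Sigma` (N x N), `mean`, `X`.
#' @export
op_covariance <- function(spec, params, pb) {
  stopifnot(spec$mode == "OP")
  N <- nrow(pb$P); C <- ncol(pb$P)
  Vfull <- expand_V(spec$structure, params, C)
  v <- params$sigma_alpha2 +
    rowSums((pb$P %*% Vfull) * pb$P) + pb$nu_op
  Sigma <- diag(v, N)
  if (!is.null(spec$batch)) {
    Z <- batch_Z(spec$batch, "op")
    Sigma <- Sigma + params$batch_var * tcrossprod(Z)
  }
  check_pd(Sigma, params)
  X <- op_design(pb$P, spec$covariates)
  list(Sigma = Sigma, mean = drop(X %*% params$beta), X = X)
}

expand_V <- function(structure, params, C) {
  V <- params$V
  switch(structure,
         hom = matrix(0, C, C),
         iid = diag(V[1, 1], C),
         free = diag(diag(as.matrix(V)), C),
         full = as.matrix(V))
}

check_pd <- function(Sigma, params, tol = 1e-10) {
  ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < tol)
    stop(sprintf(paste0("covariance not positive definite (min eigenvalue ",
                        "%.3g) at sigma_alpha2=%.3g, diag(V)=%s"),
                 ev, params$sigma_alpha2,
                 paste(format(diag(params$V), digits = 3), collapse = ",")))
  invisible(TRUE)
}
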