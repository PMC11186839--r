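# Transcriptome-level summaries of fitted models: proportion-weighted
# variance decomposition and between-cell-type correlations from the Full
# model.

#' Variance decomposition of a gene on the standardized OP scale
#'
#' Splits the total variance of standardized overall pseudobulk into the
#' variance of the fitted fixed-effect predictor (cell-type means weighted
#' by proportions plus covariates), the batch variance, the shared
#' interindividual variance sigma_alpha2, the proportion-weighted cell
#' type-specific variance `sum_c w_c V_cc` with `w_c` the mean proportion
#' of cell type c, and the mean noise variance. Shares are normalized to
#' sum to 1.
#'
#' @param fit_free a converged Free-model `ctmm_fit`.
#' @param pb the `pseudobulk` the model was fitted to.
#' @return list of shares: `share_covariates`, `share_batch`,
#'   `share_alpha`, `share_ct_specific`, `share_nu`, plus the raw
#'   components in `components`.
#' @export
variance_shares <- function(fit_free, pb) {
  stopifnot(inherits(fit_free, "ctmm_fit"))
  if (!fit_free$converged) stop("free fit did not converge")
  spec <- fit_free$spec
  C <- fit_free$C
  w <- colMeans(pb$P)
  # fixed predictor on the OP scale: proportion-weighted cell-type means
  # plus covariate terms
  beta <- fit_free$params$beta
  pred <- drop(pb$P %*% beta[seq_len(C)])
  if (!is.null(spec$covariates))
    pred <- pred + drop(spec$covariates %*% beta[-seq_len(C)])
  comp <- c(covariates = stats::var(pred),
            batch = fit_free$params$batch_var,
            alpha = fit_free$params$sigma_alpha2,
            ct_specific = sum(w * diag(fit_free$params$V)),
            nu = mean(pb$nu_op))
  total <- sum(comp)
  if (total <= 0) stop("non-positive total variance in decomposition")
  sh <- comp / total
  list(share_covariates = unname(sh["covariates"]),
       share_batch = unname(sh["batch"]),
       share_alpha = unname(sh["alpha"]),
       share_ct_specific = unname(sh["ct_specific"]),
       share_nu = unname(sh["nu"]),
       components = comp)
}

#' Between-cell-type correlations from a Full-model fit
#'
#' Converts the fitted Full-model covariance V into a correlation matrix,
#' `corr_cc' = V_cc' / sqrt(V_cc V_c'c')`. Genes with any negative
#' diagonal entry are flagged excluded (correlations undefined); a zero
#' diagonal entry yields NA for the affected pairs.
#'
#' @param fit_full a Full-model `ctmm_fit`.
#' @return list with `correlations` (C x C or all-NA when excluded) and
#'   `excluded` flag.
#' @export
full_model_correlations <- function(fit_full) {
  stopifnot(inherits(fit_full, "ctmm_fit"))
  if (fit_full$spec$structure != "full") stop("need a full-model fit")
  V <- fit_full$params$V
  d <- diag(V)
  if (any(d < 0))
    return(list(correlations = matrix(NA_real_, nrow(V), ncol(V)),
                excluded = TRUE))
  s <- sqrt(d)
  denom <- outer(s, s)
  corr <- V / denom
  corr[denom == 0] <- NA_real_
  diag(corr)[d > 0] <- 1
  list(correlations = corr, excluded = FALSE)
}
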