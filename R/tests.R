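# Tests for cell type-specific variance (Free vs Hom) and for mean
# differentiation, with Fisher-information or delete-one jackknife
# precision matrices.

new_test <- function(statistic, df, p_value, family) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 family = family),
            class = "ctmm_test")
}

#' @export
print.ctmm_test <- function(x, ...) {
  cat(sprintf("<ctmm_test> %s: stat = %.4g, df = %s, p = %.4g\n",
              x$family, x$statistic, paste(x$df, collapse = "/"), x$p_value))
  invisible(x)
}

#' Likelihood-ratio test of Free vs Hom
#'
#' Compares the (restricted) likelihoods of the Free and Hom models;
#' `2 * (loglik_free - loglik_hom)` is referred to a chi-square with C
#' degrees of freedom, one per cell type-specific variance added by the
#' Free model. Because negative variance components are allowed during
#' fitting, the null is interior and the plain chi-square reference (not a
#' boundary mixture) is used. Negative statistics are clipped to zero.
#'
#' @param fit_free,fit_hom converged `ctmm_fit`s of the Free and Hom
#'   models on the same data, covariates and method.
#' @return A `ctmm_test`.
#' @export
lrt_free_vs_hom <- function(fit_free, fit_hom) {
  if (fit_free$spec$structure != "free" || fit_hom$spec$structure != "hom")
    stop("need a free fit and a hom fit")
  if (fit_free$method == "he" || fit_hom$method == "he")
    stop("LRT requires a likelihood-based fit (ml or reml)")
  if (fit_free$method != fit_hom$method ||
      fit_free$spec$mode != fit_hom$spec$mode || fit_free$N != fit_hom$N)
    stop("fits are not nested on identical data")
  C <- fit_free$C
  stat <- max(0, 2 * (fit_free$objective - fit_hom$objective))
  new_test(stat, C, stats::pchisq(stat, df = C, lower.tail = FALSE), "lrt")
}

#' Wald F-test for cell type-specific variance
#'
#' Tests the null `diag(V) = 0` in the Free model with the quadratic form
#' `Vdiag' Prec Vdiag / C` referred to F(C, N - R), where R = 2C + 1 is the
#' Free-model parameter count. The precision of the V diagonal comes either
#' from the inverse Fisher information (numerical Hessian of the objective
#' at the optimum) or from a delete-one jackknife ([jackknife_fit()]).
#'
#' @param fit_free a converged Free-model `ctmm_fit`.
#' @param pb the `pseudobulk` the model was fitted to.
#' @param precision_source "jackknife" or "fisher".
#' @param jack optionally, a precomputed `jackknife_ensemble`.
#' @param full_precision use the full-parameter precision with a selection
#'   matrix instead of inverting the V-diagonal covariance sub-block.
#' @return A `ctmm_test`.
#' @export
wald_variance_test <- function(fit_free, pb,
                               precision_source = c("jackknife", "fisher"),
                               jack = NULL, full_precision = FALSE) {
  precision_source <- match.arg(precision_source)
  stopifnot(fit_free$spec$structure == "free")
  C <- fit_free$C; N <- fit_free$N
  R <- 2 * C + 1
  vd <- diag(fit_free$params$V)
  if (precision_source == "jackknife") {
    if (is.null(jack)) jack <- jackknife_fit(pb, fit_free)
    theta_cov <- jack$covariance
    sel <- jack$index$v_diag
  } else {
    theta_cov <- fisher_covariance(fit_free, pb)
    sel <- fisher_vdiag_index(fit_free)
  }
  fam <- paste0("wald_", if (precision_source == "jackknife") "jackknife" else "fisher")
  stat <- quad_form_stat(vd, theta_cov, sel, full_precision)
  new_test(stat / C, c(C, N - R),
           stats::pf(stat / C, C, N - R, lower.tail = FALSE), fam)
}

quad_form_stat <- function(est, theta_cov, sel, full_precision) {
  if (full_precision) {
    prec <- tryCatch(solve(theta_cov), error = function(e)
      stop("singular precision matrix in Wald test"))
    sub <- prec[sel, sel, drop = FALSE]
    # selection-matrix form: project the full precision
    return(drop(t(est) %*% sub %*% est))
  }
  sub <- theta_cov[sel, sel, drop = FALSE]
  ev <- eigen(sub, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("precision sub-block not positive definite (min eig %.3g)",
                 min(ev)))
  drop(t(est) %*% solve(sub) %*% est)
}

# Numerical Fisher information: central-difference Hessian of the
# (restricted) log-likelihood in the packed parameterization.
fisher_covariance <- function(fit, pb, h = 1e-4) {
  spec <- fit$spec
  C <- fit$C
  has_batch <- !is.null(spec$batch)
  restricted <- fit$method == "reml"
  cache <- quads_cache(spec, pb)
  f <- function(theta) {
    params <- unpack_theta(theta, spec$structure, C, has_batch)
    q <- sigma_quads(spec, params, pb, cache)
    if (is.null(q)) return(NA_real_)
    r <- if (restricted) reml_from_quads(q) else ml_from_quads(q)
    if (is.null(r)) return(NA_real_)
    if (restricted) r$rloglik else r$loglik
  }
  th <- fit$theta
  p <- length(th)
  Hm <- matrix(NA_real_, p, p)
  step <- pmax(abs(th), 1) * h
  for (a in seq_len(p)) for (b in a:p) {
    ea <- eb <- rep(0, p); ea[a] <- step[a]; eb[b] <- step[b]
    Hm[a, b] <- Hm[b, a] <-
      (f(th + ea + eb) - f(th + ea - eb) - f(th - ea + eb) + f(th - ea - eb)) /
      (4 * step[a] * step[b])
  }
  if (anyNA(Hm)) stop("Fisher information undefined near the optimum")
  FI <- -Hm
  tryCatch(solve(FI), error = function(e)
    stop("singular Fisher information matrix"))
}

fisher_vdiag_index <- function(fit) {
  # packed theta for the free model: (sigma_alpha2, V_11..V_CC, [batch])
  1L + seq_len(fit$C)
}

#' Delete-one jackknife of a fitted model
#'
#' Refits the model after excluding each individual in turn (all its cell
#' types), warm-starting at the full-sample optimum, and returns the
#' leave-one-out parameter estimates together with the delete-one jackknife
#' covariance of the full-sample estimator:
#' `cov = ((N-1)/N) * sum_i (theta_(-i) - mean)(theta_(-i) - mean)'`.
#'
#' The parameter vector collects the fixed effects followed by the variance
#' components; `$index` records which columns hold the cell-type means and
#' the V diagonal.
#'
#' @param pb the `pseudobulk` the model was fitted to.
#' @param fit a converged `ctmm_fit`.
#' @param n_restarts restarts for any leave-one-out refit that fails.
#' @return A `jackknife_ensemble`: list with `estimates` (N x p),
#'   `covariance`, `precision`, `index`.
#' @export
jackknife_fit <- function(pb, fit, n_restarts = 10) {
  spec <- fit$spec
  N <- fit$N; C <- fit$C
  if (N < fit$r_params + 2) stop("too few individuals for the jackknife")
  ests <- NULL
  for (i in seq_len(N)) {
    pbi <- drop_individual(pb, i)
    speci <- spec
    if (!is.null(spec$covariates))
      speci$covariates <- spec$covariates[-i, , drop = FALSE]
    if (!is.null(spec$batch)) speci$batch <- droplevels(spec$batch[-i])
    fi <- if (fit$method == "he") fit_he(pbi, speci)
          else fit_likelihood(pbi, speci, fit$method, n_restarts = n_restarts,
                              init = fit$theta)
    if (!fi$converged)
      stop(sprintf("leave-one-out refit failed for individual %s",
                   pb$individuals[i]))
    th <- c(fi$params$beta[seq_len(C)], fi$params$sigma_alpha2,
            diag(fi$params$V))
    ests <- rbind(ests, th)
  }
  colnames(ests) <- c(paste0("beta_", seq_len(C)), "sigma_alpha2",
                      paste0("V_", seq_len(C)))
  ctr <- sweep(ests, 2, colMeans(ests))
  covm <- (N - 1) / N * crossprod(ctr)
  prec <- tryCatch(solve(covm), error = function(e) NULL)
  structure(list(estimates = ests, covariance = covm, precision = prec,
                 index = list(beta = seq_len(C),
                              sigma_alpha2 = C + 1L,
                              v_diag = C + 1L + seq_len(C))),
            class = "jackknife_ensemble")
}

drop_individual <- function(pb, i) {
  keep <- setdiff(seq_len(nrow(pb$y)), i)
  out <- pb
  for (f in c("y", "nu", "n", "P", "mask")) out[[f]] <- pb[[f]][keep, , drop = FALSE]
  out$y_op <- pb$y_op[keep]; out$nu_op <- pb$nu_op[keep]
  out$individuals <- pb$individuals[keep]
  out
}

#' Wald F-test for mean differentiation across cell types
#'
#' Tests the null `beta_c = beta_c'` for all cell types using the contrast
#' of successive differences. beta is the GLS estimate under the fitted
#' Free-model covariance, with precision from the jackknife (which refits
#' the variance components in every leave-one-out replicate). With an HE
#' fit, beta and the test are based on ordinary least squares. The
#' statistic is referred to F(C - 1, N - R) with R = 2C + 1.
#'
#' @inheritParams jackknife_fit
#' @param jack optionally, a precomputed `jackknife_ensemble`.
#' @return A `ctmm_test`.
#' @export
mean_differentiation_test <- function(pb, fit, jack = NULL) {
  C <- fit$C; N <- fit$N
  R <- 2 * C + 1
  beta_ct <- gls_beta(pb, fit)$beta[seq_len(C)]
  if (is.null(jack)) jack <- jackknife_fit(pb, fit)
  bcov <- jack$covariance[jack$index$beta, jack$index$beta, drop = FALSE]
  L <- contrast_successive(C)
  d <- drop(L %*% beta_ct)
  Vd <- L %*% bcov %*% t(L)
  ev <- eigen(Vd, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("contrast covariance not positive definite")
  stat <- drop(t(d) %*% solve(Vd) %*% d) / (C - 1)
  fam <- if (fit$method == "he") "mean_ols" else "mean_wald_jackknife"
  new_test(stat, c(C - 1, N - R),
           stats::pf(stat, C - 1, N - R, lower.tail = FALSE), fam)
}

contrast_successive <- function(C) {
  L <- matrix(0, C - 1, C)
  for (k in seq_len(C - 1)) { L[k, k] <- 1; L[k, k + 1] <- -1 }
  L
}

#' Bonferroni correction across genes
#'
#' @param p_values numeric vector of per-gene p-values.
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `significant` (logical flags, `p < alpha / n`) and
#'   `threshold`.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop("empty p-value list")
  thr <- alpha / length(p_values)
  list(significant = !is.na(p_values) & p_values < thr, threshold = thr)
}
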