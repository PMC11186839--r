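# Fitting the variance components: ML and REML by quasi-Newton optimization
# of the (restricted) likelihood with the fixed effects profiled out by GLS,
# and Haseman-Elston (HE) method-of-moments in closed form.

# ---- parameter packing ----------------------------------------------------

theta_length <- function(structure, C, has_batch) {
  nb <- as.integer(has_batch)
  switch(structure,
         hom = 1L + nb, iid = 2L + nb, free = C + 1L + nb,
         full = C * (C + 1L) / 2L + nb)
}

unpack_theta <- function(theta, structure, C, has_batch) {
  nb <- as.integer(has_batch)
  bv <- if (has_batch) theta[length(theta)] else 0
  core <- if (has_batch) theta[-length(theta)] else theta
  if (structure == "hom") {
    sa <- core[1]; V <- matrix(0, C, C)
  } else if (structure == "iid") {
    sa <- core[1]; V <- diag(core[2], C)
  } else if (structure == "free") {
    sa <- core[1]; V <- diag(core[-1], C)
  } else {
    sa <- 0
    V <- matrix(0, C, C)
    V[lower.tri(V, diag = TRUE)] <- core
    V <- V + t(V) - diag(diag(V), C)
  }
  variance_components(beta = NULL, sigma_alpha2 = sa, V = V, batch_var = bv)
}

pack_theta <- function(params, structure, has_batch) {
  C <- ncol(params$V)
  core <- switch(structure,
                 hom = params$sigma_alpha2,
                 iid = c(params$sigma_alpha2, params$V[1, 1]),
                 free = c(params$sigma_alpha2, diag(params$V)),
                 full = params$V[lower.tri(params$V, diag = TRUE)])
  if (has_batch) c(core, params$batch_var) else core
}

# ---- likelihood fitters ---------------------------------------------------

fit_likelihood <- function(pb, spec, method, n_restarts = 10,
                           nelder_refine = FALSE, init = NULL) {
  C <- ncol(pb$y)
  has_batch <- !is.null(spec$batch)
  cache <- quads_cache(spec, pb)
  prov <- objective_provider(spec, pb, method, cache)
  negll <- prov$fn
  p <- theta_length(spec$structure, C, has_batch)
  n_obs <- if (spec$mode == "CTP") nrow(pb$y) * C else nrow(pb$y)
  if (n_obs <= n_params(spec$structure, C))
    stop("fewer observations than model parameters")
  s2 <- init_scale(pb, spec)
  start <- if (!is.null(init)) init else default_start(spec$structure, C, s2,
                                                      has_batch, pb)
  attempt <- function(par) {
    fit <- tryCatch(
      stats::optim(par, negll, gr = prov$gr, method = "L-BFGS-B",
                   control = list(maxit = 500, factr = 1e5)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e9) return(NULL)
    if (nelder_refine) {
      fit2 <- tryCatch(
        stats::optim(fit$par, negll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit2) && is.finite(fit2$value) && fit2$value < fit$value)
        fit <- fit2
    }
    fit
  }
  best <- attempt(start)
  n_used <- 0L
  if (is.null(best) || best$convergence != 0) {
    # random restarts: each variance component from |N(0, s2/2)|
    for (r in seq_len(n_restarts)) {
      n_used <- n_used + 1L
      par <- abs(stats::rnorm(p, 0, sqrt(s2 / 2)))
      cand <- attempt(par)
      if (!is.null(cand) &&
          (is.null(best) || cand$value < best$value - 1e-8 ||
             (best$convergence != 0 && cand$convergence == 0)))
        best <- cand
      if (!is.null(best) && best$convergence == 0) break
    }
  }
  if (is.null(best)) {
    return(new_fit(params = unpack_theta(rep(NA_real_, p), spec$structure,
                                         C, has_batch),
                   objective = NA_real_, converged = FALSE,
                   n_restarts_used = n_used, method = method, spec = spec,
                   N = nrow(pb$y), C = C))
  }
  params <- unpack_theta(best$par, spec$structure, C, has_batch)
  q <- sigma_quads(spec, params, pb, cache)
  sol <- ml_from_quads(q)
  params$beta <- sol$beta
  new_fit(params = params, objective = -best$value,
          converged = best$convergence == 0, n_restarts_used = n_used,
          method = method, spec = spec, N = nrow(pb$y), C = C,
          theta = best$par)
}

init_scale <- function(pb, spec) {
  y <- if (spec$mode == "CTP") as.vector(pb$y) else pb$y_op
  stats::var(y, na.rm = TRUE)
}

default_start <- function(structure, C, s2, has_batch, pb) {
  mnu <- mean(pb$nu, na.rm = TRUE)
  excess <- max(s2 - mnu, 0.05 * s2)
  core <- switch(structure,
                 hom = excess,
                 iid = c(excess / 2, excess / 2),
                 free = c(excess / 2, rep(excess / 2, C)),
                 full = {
                   V0 <- diag(excess, C)
                   V0[lower.tri(V0, diag = TRUE)]
                 })
  if (has_batch) c(core, excess / 4) else core
}

new_fit <- function(params, objective, converged, n_restarts_used, method,
                    spec, N, C, theta = NULL) {
  structure(list(params = params, objective = objective,
                 converged = converged, n_restarts_used = n_restarts_used,
                 method = method, spec = spec, N = N, C = C, theta = theta,
                 r_params = n_params(spec$structure, C)),
            class = "ctmm_fit")
}

#' @export
print.ctmm_fit <- function(x, ...) {
  cat(sprintf("<ctmm_fit> %s / %s / %s: %s (objective %.4f%s)\n",
              toupper(x$method), x$spec$structure, x$spec$mode,
              if (x$converged) "converged" else "NOT converged",
              x$objective,
              if (x$n_restarts_used > 0)
                sprintf(", %d restarts", x$n_restarts_used) else ""))
  if (x$converged) print(x$params)
  invisible(x)
}

#' Fit by maximum likelihood
#'
#' Maximizes the Gaussian likelihood over the variance components by BFGS,
#' with the fixed effects profiled out by generalized least squares at each
#' step. Negative variance components are permitted; parameter vectors whose
#' implied total covariance is not positive definite are rejected. If the
#' initial attempt fails, up to `n_restarts` random restarts are run, each
#' drawing variance components from |N(0, s2/2)| with s2 the sample variance
#' of the pseudobulk.
#'
#' @param pb a complete `pseudobulk`.
#' @param spec a [ctmm_spec].
#' @param n_restarts maximum number of random restarts after a failed
#'   initial attempt.
#' @param nelder_refine refine the BFGS solution with Nelder-Mead
#'   iterations (off by default).
#' @param init optional starting parameter vector (packed theta).
#' @return A `ctmm_fit` with elements `params`, `objective` (final
#'   log-likelihood), `converged`, `n_restarts_used`, `method`.
#' @export
fit_ml <- function(pb, spec, n_restarts = 10, nelder_refine = FALSE,
                   init = NULL) {
  fit_likelihood(pb, spec, "ml", n_restarts, nelder_refine, init)
}

#' Fit by restricted maximum likelihood
#'
#' As [fit_ml()] but maximizing the restricted likelihood, which
#' residualizes the fixed effects and removes their estimation cost from
#' the variance components.
#'
#' @inheritParams fit_ml
#' @return A `ctmm_fit`.
#' @export
fit_reml <- function(pb, spec, n_restarts = 10, nelder_refine = FALSE,
                     init = NULL) {
  fit_likelihood(pb, spec, "reml", n_restarts, nelder_refine, init)
}

# ---- Haseman-Elston -------------------------------------------------------

# Per-block C x C design matrices of each variance component (CTP mode).
he_blocks <- function(structure, C) {
  J <- matrix(1, C, C)
  if (structure == "hom") return(list(J))
  if (structure == "iid") return(list(J, diag(C)))
  if (structure == "free") {
    c(list(J), lapply(seq_len(C), function(c0) {
      E <- matrix(0, C, C); E[c0, c0] <- 1; E
    }))
  } else { # full: vech order, no shared term
    out <- list()
    for (c2 in seq_len(C)) for (c1 in c2:C) {
      E <- matrix(0, C, C)
      E[c1, c2] <- E[c2, c1] <- 1
      out <- c(out, list(E))
    }
    out
  }
}

he_theta_to_params <- function(theta, structure, C) {
  if (structure == "hom") {
    variance_components(NULL, theta[1], matrix(0, C, C))
  } else if (structure == "iid") {
    variance_components(NULL, theta[1], diag(theta[2], C))
  } else if (structure == "free") {
    variance_components(NULL, theta[1], diag(theta[-1], C))
  } else {
    V <- matrix(0, C, C)
    k <- 1L
    for (c2 in seq_len(C)) for (c1 in c2:C) {
      V[c1, c2] <- V[c2, c1] <- theta[k]; k <- k + 1L
    }
    variance_components(NULL, 0, V)
  }
}

#' Fit by Haseman-Elston regression (method of moments)
#'
#' Regresses the empirical second-moment matrix of the OLS-residualized
#' pseudobulk, with the known noise variances `diag(nu)` subtracted, onto
#' the covariance design of each variance component by least squares. The
#' solution is closed-form and deterministic; the large cross-product
#' matrices are never materialized (trace identities are used instead).
#' The fixed effects are estimated by OLS, as the method does not model
#' the residual covariance.
#'
#' @inheritParams fit_ml
#' @return A `ctmm_fit` with `method = "he"`; `objective` is the residual
#'   moment loss of the least-squares system.
#' @export
fit_he <- function(pb, spec) {
  if (!is.null(spec$batch))
    stop("HE fitting does not support a blocked batch random effect; ",
         "use fit_reml or fit_ml")
  C <- ncol(pb$y)
  if (spec$mode == "CTP") he_ctp(pb, spec, C) else he_op(pb, spec, C)
}

he_ctp <- function(pb, spec, C) {
  if (anyNA(pb$y)) stop("missing pseudobulk entries: impute before fitting")
  N <- nrow(pb$y)
  X <- ctp_design(N, C, spec$covariates)
  y <- as.vector(t(pb$y))
  K <- ncol(X)
  XtX <- crossprod(X)
  Bx <- tryCatch(solve(XtX), error = function(e)
    stop("singular fixed design in HE fit"))
  beta <- drop(Bx %*% crossprod(X, y))
  e <- y - drop(X %*% beta)
  E <- matrix(e, N, C, byrow = TRUE)
  blocks <- he_blocks(spec$structure, C)
  p <- length(blocks)
  # S(B) = sum_i X_i' B X_i and the nu-weighted analogues; without
  # covariates X_i = I_C for every individual, so these collapse.
  if (K == C) {
    csnu <- colSums(pb$nu); csnu2 <- colSums(pb$nu^2)
    S_of <- function(B) N * B
    S_nu <- function(B) B %*% diag(csnu, C)
    G_D <- diag(csnu, C); G_D2 <- diag(csnu2, C)
  } else {
    Xi <- lapply(seq_len(N), function(i)
      X[((i - 1) * C + 1):(i * C), , drop = FALSE])
    S_of <- function(B) Reduce(`+`, lapply(Xi, function(x) crossprod(x, B %*% x)))
    S_nu <- function(B) {
      acc <- matrix(0, K, K)
      for (i in seq_len(N))
        acc <- acc + crossprod(Xi[[i]], B %*% (pb$nu[i, ] * Xi[[i]]))
      acc
    }
    G_D <- Reduce(`+`, lapply(seq_len(N), function(i)
      crossprod(Xi[[i]], pb$nu[i, ] * Xi[[i]])))
    G_D2 <- Reduce(`+`, lapply(seq_len(N), function(i)
      crossprod(Xi[[i]], pb$nu[i, ]^2 * Xi[[i]])))
  }
  G <- lapply(blocks, S_of)
  TT <- matrix(0, p, p)
  tvec <- numeric(p)
  for (k in seq_len(p)) {
    Bk <- blocks[[k]]
    for (l in k:p) {
      Bl <- blocks[[l]]
      val <- N * sum(Bk * t(Bl)) -
        2 * sum(Bx * t(S_of(Bk %*% Bl))) +
        sum((Bx %*% G[[k]]) * t(Bx %*% G[[l]]))
      TT[k, l] <- TT[l, k] <- val
    }
    # tr(M A_k M D) pieces
    trAD <- sum(sweep(pb$nu, 2, diag(Bk), "*"))
    trHAD <- sum(Bx * t(S_nu(Bk)))
    trHAHD <- sum((Bx %*% G[[k]]) * t(Bx %*% G_D))
    tvec[k] <- sum((E %*% Bk) * E) - (trAD - 2 * trHAD + trHAHD)
  }
  theta <- tryCatch(solve(TT, tvec), error = function(e)
    stop("singular moment design in HE fit (collinear cell types?)"))
  # residual moment loss ||ee' - M D M - sum theta_k M A_k M||_F^2
  ee2 <- sum(e^2)^2
  eDe <- sum(e^2 * as.vector(t(pb$nu)))
  trMDMD <- sum(pb$nu^2) - 2 * sum(Bx * t(G_D2)) +
    sum((Bx %*% G_D) * t(Bx %*% G_D))
  tt <- ee2 - 2 * eDe + trMDMD
  loss <- tt - 2 * sum(theta * tvec) + drop(t(theta) %*% TT %*% theta)
  params <- he_theta_to_params(theta, spec$structure, C)
  params$beta <- beta
  new_fit(params = params, objective = loss, converged = TRUE,
          n_restarts_used = 0L, method = "he", spec = spec, N = N, C = C)
}

he_op <- function(pb, spec, C) {
  N <- nrow(pb$P)
  X <- op_design(pb$P, spec$covariates)
  y <- pb$y_op
  Bx <- tryCatch(solve(crossprod(X)), error = function(e)
    stop("singular fixed design in HE fit"))
  beta <- drop(Bx %*% crossprod(X, y))
  e <- y - drop(X %*% beta)
  H <- X %*% Bx %*% t(X)
  Mm <- diag(N) - H
  # diagonal designs a_k (length N) per component
  P <- pb$P
  if (spec$structure == "hom") {
    av <- list(rep(1, N))
  } else if (spec$structure == "iid") {
    av <- list(rep(1, N), rowSums(P^2))
  } else if (spec$structure == "free") {
    av <- c(list(rep(1, N)), lapply(seq_len(C), function(c0) P[, c0]^2))
  } else {
    av <- list()
    for (c2 in seq_len(C)) for (c1 in c2:C) {
      av <- c(av, list(if (c1 == c2) P[, c1]^2 else 2 * P[, c1] * P[, c2]))
    }
  }
  p <- length(av)
  MA <- lapply(av, function(a) Mm %*% (a * Mm))  # M diag(a) M
  Dn <- pb$nu_op
  MDM <- Mm %*% (Dn * Mm)
  TT <- matrix(0, p, p)
  tvec <- numeric(p)
  tgt <- tcrossprod(e) - MDM
  for (k in seq_len(p)) {
    for (l in k:p) TT[k, l] <- TT[l, k] <- sum(MA[[k]] * MA[[l]])
    tvec[k] <- sum(MA[[k]] * tgt)
  }
  theta <- tryCatch(solve(TT, tvec), error = function(e)
    stop("singular moment design in HE fit (collinear cell types?)"))
  loss <- sum(tgt^2) - 2 * sum(theta * tvec) + drop(t(theta) %*% TT %*% theta)
  params <- he_theta_to_params(theta, spec$structure, C)
  params$beta <- beta
  new_fit(params = params, objective = loss, converged = TRUE,
          n_restarts_used = 0L, method = "he", spec = spec, N = N, C = C)
}

# ---- GLS fixed effects ----------------------------------------------------

#' Generalized least squares estimate of the cell-type means
#'
#' Computes the GLS solution for the fixed effects under the covariance of
#' a fitted model (typically the Free model). For HE fits, ordinary least
#' squares is used instead, as HE does not produce a reliable residual
#' covariance.
#'
#' @param pb the `pseudobulk` the model was fitted to.
#' @param fit a converged `ctmm_fit`.
#' @return list with `beta` and its model-based covariance `vcov`.
#' @export
gls_beta <- function(pb, fit) {
  stopifnot(inherits(fit, "ctmm_fit"))
  spec <- fit$spec
  if (fit$method == "he") {
    X <- if (spec$mode == "CTP") ctp_design(nrow(pb$y), ncol(pb$y), spec$covariates)
         else op_design(pb$P, spec$covariates)
    y <- if (spec$mode == "CTP") as.vector(t(pb$y)) else pb$y_op
    XtXi <- solve(crossprod(X))
    beta <- drop(XtXi %*% crossprod(X, y))
    s2 <- sum((y - X %*% beta)^2) / (length(y) - ncol(X))
    return(list(beta = beta, vcov = s2 * XtXi))
  }
  q <- sigma_quads(spec, fit$params, pb)
  if (is.null(q)) stop("fitted covariance is not positive definite")
  sol <- ml_from_quads(q)
  if (is.null(sol)) stop("singular design in GLS")
  list(beta = sol$beta, vcov = solve(sol$XtSiX))
}
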