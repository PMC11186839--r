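test_that("REML with one cell type matches the closed-form variance estimate", {
  # C = 1, hom: y_i = beta + alpha_i + delta_i with known equal nu.
  # REML of sigma_alpha2 is the sample variance minus nu.
  set.seed(41)
  N <- 60; nu0 <- 0.12
  y <- matrix(rnorm(N, 2, sqrt(0.3 + nu0)), N, 1)
  pb <- as_pseudobulk(y, matrix(nu0, N, 1))
  fit <- fit_reml(pb, ctmm_spec("hom", "CTP"))
  expect_true(fit$converged)
  expect_equal(fit$params$sigma_alpha2, var(y[, 1]) - nu0, tolerance = 1e-5)
  expect_equal(unname(fit$params$beta), mean(y[, 1]), tolerance = 1e-6)
})

test_that("ML and REML recover simulated variance components", {
  set.seed(42)
  cfg <- sim_config(500, structure = "hom", sigma_alpha2 = 0.3, seed = 900)
  reps <- 60
  sa_hat <- v_hat <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_ctp(cfg, r)
    f <- fit_reml(sim$pb, ctmm_spec("free", "CTP"))
    sa_hat[r] <- f$params$sigma_alpha2
    v_hat[r] <- mean(diag(f$params$V))
  }
  expect_lt(abs(mean(sa_hat) - 0.3), 3 * sd(sa_hat) / sqrt(reps))
  # free fit on hom-generated data: V entries centered at zero
  expect_lt(abs(mean(v_hat)), 3 * sd(v_hat) / sqrt(reps))
})

test_that("HE matches a naive dense method-of-moments oracle", {
  # oracle: OLS-residualize, build the moment system on vec(ee' - M D M)
  # with dense NC x NC matrices, solve by lm
  dense_he <- function(pb, spec) {
    N <- nrow(pb$y); C <- ncol(pb$y)
    X <- ctvmm:::ctp_design(N, C, spec$covariates)
    y <- as.vector(t(pb$y))
    H <- X %*% solve(crossprod(X)) %*% t(X)
    M <- diag(N * C) - H
    e <- drop(M %*% y)
    blocks <- ctvmm:::he_blocks(spec$structure, C)
    A_full <- lapply(blocks, function(B)
      M %*% as.matrix(Matrix::bdiag(rep(list(B), N))) %*% M)
    D <- diag(as.vector(t(pb$nu)))
    target <- tcrossprod(e) - M %*% D %*% M
    Tm <- sapply(A_full, as.vector)
    drop(solve(crossprod(Tm), crossprod(Tm, as.vector(target))))
  }
  for (st in c("hom", "free", "full")) {
    pb <- random_pb(7, 3, seed = 50 + nchar(st))
    spec <- ctmm_spec(st, "CTP")
    fit <- fit_he(pb, spec)
    theta <- switch(st,
                    hom = fit$params$sigma_alpha2,
                    free = c(fit$params$sigma_alpha2, diag(fit$params$V)),
                    full = fit$params$V[lower.tri(fit$params$V, diag = TRUE)])
    ref <- dense_he(pb, spec)
    if (st == "full") {
      # oracle ordering is vech by column; ours packs columnwise too
      expect_equal(unname(theta), unname(ref), tolerance = 1e-8)
    } else {
      expect_equal(unname(theta), unname(ref), tolerance = 1e-8)
    }
  }
  # with covariates too
  set.seed(60)
  pb <- random_pb(9, 3, seed = 61)
  covm <- matrix(rnorm(9), 9, 1)
  spec <- ctmm_spec("free", "CTP", covariates = covm)
  expect_equal(unname(c(fit_he(pb, spec)$params$sigma_alpha2,
                        diag(fit_he(pb, spec)$params$V))),
               unname(dense_he(pb, spec)), tolerance = 1e-8)
})

test_that("HE is unbiased under the Hom model and deterministic", {
  cfg <- sim_config(150, structure = "hom", seed = 300)
  reps <- 150
  v1 <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_ctp(cfg, r)
    v1[r] <- diag(fit_he(sim$pb, ctmm_spec("free", "CTP"))$params$V)[1]
  }
  expect_lt(abs(mean(v1)), 3 * sd(v1) / sqrt(reps))
  sim <- simulate_ctp(cfg, 1)
  f1 <- fit_he(sim$pb, ctmm_spec("free", "CTP"))
  f2 <- fit_he(sim$pb, ctmm_spec("free", "CTP"))
  expect_identical(f1$params, f2$params)
})

test_that("HE agrees with ML on large samples", {
  sim <- simulate_ctp(sim_config(2000, structure = "free", seed = 77), 1)
  he <- fit_he(sim$pb, ctmm_spec("free", "CTP"))
  ml <- fit_ml(sim$pb, ctmm_spec("free", "CTP"))
  # both are consistent for the same parameters; at N = 2000 their
  # difference is within a few Monte-Carlo standard errors (~0.007)
  expect_lt(max(abs(diag(he$params$V) - diag(ml$params$V))), 0.02)
  expect_lt(abs(he$params$sigma_alpha2 - ml$params$sigma_alpha2), 0.02)
})

test_that("likelihood methods are more precise than HE", {
  cfg <- sim_config(80, structure = "free", seed = 500)
  reps <- 100
  v_reml <- v_he <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_ctp(cfg, r)
    v_reml[r] <- diag(fit_reml(sim$pb, ctmm_spec("free", "CTP"))$params$V)[1]
    v_he[r] <- diag(fit_he(sim$pb, ctmm_spec("free", "CTP"))$params$V)[1]
  }
  expect_lte(var(v_reml), var(v_he))
})

test_that("GLS reduces to OLS under homoskedastic covariance", {
  pb <- random_pb(10, 3, seed = 71)
  pb$nu[] <- 0.1
  spec <- ctmm_spec("hom", "CTP")
  fit <- manual_fit(variance_components(rep(0, 3), 0, matrix(0, 3, 3)),
                    spec, 10, 3)
  # sigma_alpha2 = 0, V = 0, equal nu: covariance proportional to identity
  g <- gls_beta(pb, fit)
  X <- ctvmm:::ctp_design(10, 3)
  ols <- solve(crossprod(X), crossprod(X, as.vector(t(pb$y))))
  expect_equal(unname(g$beta), unname(drop(ols)), tolerance = 1e-10)
})

test_that("GLS with one cell type is the precision-weighted mean", {
  set.seed(81)
  N <- 15
  y <- matrix(rnorm(N), N, 1)
  nu <- matrix(runif(N, 0.05, 0.5), N, 1)
  pb <- as_pseudobulk(y, nu)
  sa <- 0.2
  fit <- manual_fit(variance_components(0, sa, matrix(0, 1, 1)),
                    ctmm_spec("hom", "CTP"), N, 1)
  g <- gls_beta(pb, fit)
  w <- 1 / (sa + nu[, 1])
  expect_equal(unname(g$beta), sum(w * y[, 1]) / sum(w), tolerance = 1e-10)
})

test_that("GLS recovers simulated cell-type means", {
  cfg <- sim_config(200, structure = "free", beta = c(0, 1, 2, 3), seed = 600)
  sim <- simulate_ctp(cfg, 1)
  fit <- fit_reml(sim$pb, ctmm_spec("free", "CTP"))
  g <- gls_beta(sim$pb, fit)
  se <- sqrt(diag(g$vcov))
  expect_true(all(abs(g$beta - c(0, 1, 2, 3)) < 4 * se))
})

test_that("fits report convergence, restarts, and reject tiny samples", {
  sim <- simulate_ctp(sim_config(30, structure = "free", seed = 10), 1)
  fit <- fit_reml(sim$pb, ctmm_spec("free", "CTP"))
  expect_true(fit$converged)
  expect_true(fit$n_restarts_used >= 0)
  tiny <- simulate_ctp(sim_config(8, 4, structure = "free", seed = 10), 1)
  expect_error(fit_reml(tiny$pb, ctmm_spec("free", "OP")),
               "fewer observations")
})
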