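test_that("LRT compares nested fits with C degrees of freedom", {
  sim <- simulate_ctp(sim_config(40, structure = "hom", seed = 15), 1)
  ff <- fit_reml(sim$pb, ctmm_spec("free", "CTP"))
  fh <- fit_reml(sim$pb, ctmm_spec("hom", "CTP"))
  res <- lrt_free_vs_hom(ff, fh)
  expect_equal(res$df, 4)
  expect_gte(res$statistic, 0)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # identical objectives: stat 0, p = 1
  res0 <- lrt_free_vs_hom(ff, ff_as_hom <- {h <- ff; h$spec$structure <- "hom"; h})
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # chi-square reference: C = 4, stat at the 95% quantile -> p = 0.05
  h2 <- fh; h2$objective <- ff$objective - qchisq(0.95, 4) / 2
  expect_equal(lrt_free_vs_hom(ff, h2)$p_value, 0.05, tolerance = 1e-6)
  # non-nested or mismatched inputs are refused
  expect_error(lrt_free_vs_hom(fh, fh), "free")
  he <- fit_he(sim$pb, ctmm_spec("free", "CTP"))
  expect_error(lrt_free_vs_hom(he, fh), "likelihood")
})

test_that("degrees-of-freedom bookkeeping for C = 4, N = 94", {
  # Free model parameter count R = 2C + 1 = 9
  expect_equal(ctvmm:::n_params("free", 4), 9)
  sim <- simulate_ctp(sim_config(94, structure = "free", seed = 16), 1)
  ff <- fit_reml(sim$pb, ctmm_spec("free", "CTP"))
  jk <- jackknife_fit(sim$pb, ff)
  wv <- wald_variance_test(ff, sim$pb, "jackknife", jack = jk)
  expect_equal(wv$df, c(4, 85))
  mt <- mean_differentiation_test(sim$pb, ff, jack = jk)
  expect_equal(mt$df, c(3, 85))
})

test_that("Wald statistic is zero (p = 1) when the V diagonal is zero", {
  spec <- ctmm_spec("free", "CTP")
  fit <- manual_fit(variance_components(rep(0, 3), 0.1, matrix(0, 3, 3)),
                    spec, 50, 3)
  jack <- structure(list(covariance = diag(7), precision = diag(7),
                         index = list(beta = 1:3, sigma_alpha2 = 4,
                                      v_diag = 5:7)),
                    class = "jackknife_ensemble")
  res <- wald_variance_test(fit, NULL, "jackknife", jack = jack)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("Fisher and jackknife precision give comparable Wald tests", {
  sim <- simulate_ctp(sim_config(60, structure = "free", seed = 17), 1)
  ff <- fit_reml(sim$pb, ctmm_spec("free", "CTP"))
  pf_ <- wald_variance_test(ff, sim$pb, "fisher")
  pj <- wald_variance_test(ff, sim$pb, "jackknife")
  expect_equal(pf_$df, pj$df)
  # strong simulated signal: both should reject decisively
  expect_lt(pf_$p_value, 0.01)
  expect_lt(pj$p_value, 0.01)
  # selection-matrix variant runs and stays in [0, 1]
  pj2 <- wald_variance_test(ff, sim$pb, "jackknife", full_precision = TRUE)
  expect_true(pj2$p_value >= 0 && pj2$p_value <= 1)
})

test_that("jackknife covariance is symmetric PSD and shrinks for duplicated data", {
  sim <- simulate_ctp(sim_config(30, structure = "free", seed = 18), 1)
  ff <- fit_reml(sim$pb, ctmm_spec("free", "CTP"))
  jk <- jackknife_fit(sim$pb, ff)
  expect_equal(jk$covariance, t(jk$covariance))
  ev <- eigen(jk$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_equal(nrow(jk$estimates), 30)
  # duplicated individuals: removing one copy leaves its twin, so the
  # leave-one-out estimates barely move and the precision is much larger
  # than for the same data without duplication
  sub <- ctvmm:::drop_individual  # keep 15 unique individuals
  pb15 <- sim$pb
  for (i in 30:16) pb15 <- sub(pb15, i)
  pb2 <- sim$pb
  idx <- rep(seq_len(15), each = 2)
  pb2$y <- sim$pb$y[idx, ]; pb2$nu <- sim$pb$nu[idx, ]
  pb2$n <- sim$pb$n[idx, ]; pb2$P <- sim$pb$P[idx, ]
  pb2$y_op <- sim$pb$y_op[idx]; pb2$nu_op <- sim$pb$nu_op[idx]
  pb2$individuals <- paste0("d", seq_len(30))
  ff15 <- fit_reml(pb15, ctmm_spec("free", "CTP"))
  jk15 <- jackknife_fit(pb15, ff15)
  ff2 <- fit_reml(pb2, ctmm_spec("free", "CTP"))
  jk2 <- jackknife_fit(pb2, ff2)
  expect_lt(max(diag(jk2$covariance)), 0.5 * max(diag(jk15$covariance)))
})

test_that("delete-one covariance formula matches the closed form for a mean", {
  # the jackknife covariance of the sample mean is s^2 / N
  set.seed(19)
  x <- rnorm(25)
  loo <- sapply(seq_along(x), function(i) mean(x[-i]))
  ctr <- loo - mean(loo)
  jk_var <- (25 - 1) / 25 * sum(ctr^2)
  expect_equal(jk_var, var(x) / 25, tolerance = 1e-12)
})

test_that("mean differentiation test detects a shifted cell type", {
  cfg <- sim_config(200, structure = "free", beta = c(0, 0, 0, 1), seed = 20)
  sim <- simulate_ctp(cfg, 1)
  ff <- fit_reml(sim$pb, ctmm_spec("free", "CTP"))
  mt <- mean_differentiation_test(sim$pb, ff)
  expect_equal(mt$df, c(3, 200 - 9))
  expect_lt(mt$p_value, 1e-4)
  expect_equal(mt$family, "mean_wald_jackknife")
  # HE route uses OLS and is labeled as such
  he <- fit_he(sim$pb, ctmm_spec("free", "CTP"))
  jkh <- jackknife_fit(sim$pb, he)
  mth <- mean_differentiation_test(sim$pb, he, jack = jkh)
  expect_equal(mth$family, "mean_ols")
  expect_lt(mth$p_value, 1e-4)
})

test_that("Bonferroni correction flags by the family-wise threshold", {
  b <- bonferroni(c(1e-7, 0.01, 0.9), alpha = 0.05)
  expect_equal(b$threshold, 0.05 / 3)
  expect_equal(b$significant, c(TRUE, TRUE, FALSE))
  expect_equal(bonferroni(0.04)$threshold, 0.05)
  expect_false(any(bonferroni(rep(1, 10))$significant))
  expect_error(bonferroni(numeric(0)), "empty")
  # the transcriptome-scale threshold used in practice
  expect_equal(bonferroni(rep(0.5, 11526))$threshold, 0.05 / 11526)
})

test_that("null LRT p-values are approximately uniform", {
  cfg <- sim_config(200, structure = "hom", seed = 21)
  ps <- numeric(120)
  for (r in seq_len(120)) {
    sim <- simulate_ctp(cfg, r)
    ff <- fit_reml(sim$pb, ctmm_spec("free", "CTP"))
    fh <- fit_reml(sim$pb, ctmm_spec("hom", "CTP"))
    ps[r] <- lrt_free_vs_hom(ff, fh)$p_value
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  rate <- mean(ps < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 120))
})
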