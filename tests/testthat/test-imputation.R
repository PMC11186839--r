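test_that("low-rank completion recovers a rank-1 matrix and fixes nothing else", {
  set.seed(30)
  u <- rnorm(40); v <- c(1, 2, 3, 4)
  x <- outer(u, v)
  miss <- matrix(runif(160) < 0.1, 40, 4)
  xm <- x; xm[miss] <- NA
  filled <- impute_lowrank(xm, lambda = 1e-4, rank = 1)
  expect_lt(max(abs(filled[miss] - x[miss]) / pmax(abs(x[miss]), 1)), 1e-3)
  # observed entries never altered
  expect_identical(filled[!miss], xm[!miss])
  # no missing entries: identity
  expect_identical(impute_lowrank(x), x)
  # perfectly correlated columns: hidden entry filled from the row
  xc <- cbind(u, u, u); xc[3, 2] <- NA
  fc <- impute_lowrank(xc, lambda = 1e-6, rank = 1)
  expect_equal(unname(fc[3, 2]), unname(u[3]), tolerance = 1e-2)
  # a fully missing column is refused
  xbad <- x; xbad[, 2] <- NA
  expect_error(impute_lowrank(xbad), "observed")
})

test_that("MVN imputation fills conditional means", {
  set.seed(31)
  # correlation 1: conditional mean is the linear prediction
  a <- rnorm(30)
  x <- cbind(a, 2 * a + 1)
  x[5, 2] <- NA
  f <- impute_mvn(x)
  expect_equal(unname(f[5, 2]), unname(2 * a[5] + 1), tolerance = 1e-2)
  expect_identical(f[-5, ], x[-5, ])
  # sample-independent columns: imputed value is the column mean
  b <- rnorm(30)
  b_res <- residuals(lm(b ~ a))           # sample covariance exactly 0
  xi <- cbind(a, b_res)
  xi[7, 2] <- NA
  fi <- impute_mvn(xi)
  expect_equal(unname(fi[7, 2]), mean(xi[-7, 2]), tolerance = 0.05)
})

test_that("MVN imputation error matches the analytic conditional variance", {
  set.seed(32)
  C <- 4; N <- 400
  A <- matrix(rnorm(C * C), C, C)
  Sg <- crossprod(A) + diag(0.5, C)
  L <- chol(Sg)
  x <- matrix(rnorm(N * C), N, C) %*% L
  miss <- matrix(runif(N * C) < 0.1, N, C)
  miss[rowSums(miss) == C, 1] <- FALSE   # keep at least one observed per row
  xm <- x; xm[miss] <- NA
  f <- impute_mvn(xm)
  # average analytic conditional variance over the missing entries
  cond_var <- mapply(function(i, j) {
    o <- !miss[i, ]
    drop(Sg[j, j] - Sg[j, o] %*% solve(Sg[o, o], Sg[o, j]))
  }, row(miss)[miss], col(miss)[miss])
  mse <- mean((f[miss] - x[miss])^2)
  expect_lt(abs(mse - mean(cond_var)) / mean(cond_var), 0.25)
})

test_that("transcriptome-wide imputation collapses to per-gene for G = 1", {
  set.seed(33)
  x <- outer(rnorm(20), c(1, -1, 2)) ; x[2, 3] <- NA
  expect_equal(impute_transcriptomewide_lowrank(x, lambda = 1e-4, rank = 2),
               impute_lowrank(x, lambda = 1e-4, rank = 2))
  # no missing: identity over the list
  mats <- list(matrix(rnorm(20), 10, 2), matrix(rnorm(20), 10, 2))
  expect_equal(impute_transcriptomewide_lowrank(mats), mats)
})

test_that("joint imputation beats per-gene column means on shared-factor data", {
  set.seed(34)
  N <- 30; C <- 4; G <- 12
  f1 <- rnorm(N)
  mats <- lapply(seq_len(G), function(g)
    outer(f1, rnorm(C)) + matrix(rnorm(N * C, 0, 0.1), N, C))
  # structural missingness to donate: two individuals lack two cell types
  for (m in seq_along(mats)) mats[[m]][1:2, 1:2] <- NA
  col_mean_imputer <- function(x) {
    cm <- colMeans(x, na.rm = TRUE)
    x[is.na(x)] <- matrix(cm, nrow(x), ncol(x), byrow = TRUE)[is.na(x)]
    x
  }
  acc_joint <- copy_mask_evaluate(mats, "transcriptomewide",
                                  n_replicates = 4, seed = 5)
  acc_mean <- copy_mask_evaluate(mats, col_mean_imputer,
                                 n_replicates = 4, seed = 5)
  # the column-mean imputer is constant within a cell type, so its
  # correlation is undefined (reported missing); score it as 0
  cor0 <- function(x) ifelse(is.na(x), 0, x)
  expect_gt(median(cor0(acc_joint$median_correlation)),
            median(cor0(acc_mean$median_correlation)))
  expect_lt(median(acc_joint$median_mse, na.rm = TRUE),
            median(acc_mean$median_mse, na.rm = TRUE))
})

test_that("copy-masking copies donor patterns and hits the target fraction", {
  set.seed(35)
  mask <- matrix(FALSE, 40, 4)
  mask[1:4, 1:2] <- TRUE           # donors miss cell types 1 and 2
  plan <- mask_plan(mask, fraction = 0.10, replicate_id = 1, seed = 2)
  expect_gte(sum(plan$masked), ceiling(0.10 * 160))
  # every masked recipient's new-missing set equals the donor pattern
  hit <- rowSums(plan$masked) > 0
  expect_true(all(apply(plan$masked[hit, , drop = FALSE], 1, function(z)
    identical(which(z), 1:2))))
  # recipients are distinct from donors
  expect_false(any(hit[1:4]))
  expect_error(mask_plan(matrix(FALSE, 5, 3)), "donate")
})

test_that("copy-mask evaluation scores a perfect imputer perfectly", {
  set.seed(36)
  mats <- lapply(1:3, function(g) matrix(rnorm(60), 20, 3))
  for (m in seq_along(mats)) mats[[m]][1, 1] <- NA
  truth <- mats
  perfect <- function(x) {
    g <- which(vapply(truth, function(t)
      identical(dim(t), dim(x)) && all(t[!is.na(x)] == x[!is.na(x)]), TRUE))[1]
    out <- truth[[g]]
    out[is.na(truth[[g]])] <- 0
    out
  }
  acc <- copy_mask_evaluate(mats, perfect, n_replicates = 3, seed = 7)
  expect_true(all(acc$median_mse < 1e-12, na.rm = TRUE))
  expect_true(all(abs(acc$median_correlation - 1) < 1e-12, na.rm = TRUE))
})

test_that("negative imputed noise variances are repaired by mode", {
  # OP: clamp to zero
  expect_equal(repair_negative_nu(matrix(c(-0.1, 0.2), 1), mode = "OP"),
               matrix(c(0, 0.2), 1))
  # CTP: replace with the per-cell-type max of observed raw nu
  raw <- matrix(c(0.1, 0.4, NA, 0.05, 0.02, 0.03), 3, 2)
  imp <- matrix(c(-0.3, 0.2, 0.15, 0.04, -0.5, 0.03), 3, 2)
  rep_ctp <- repair_negative_nu(imp, mode = "CTP", raw_nu = raw)
  expect_equal(rep_ctp[1, 1], 0.4)     # max observed in cell type 1
  expect_equal(rep_ctp[2, 2], 0.05)    # max observed in cell type 2
  expect_true(all(rep_ctp >= 0))
  # untouched when already nonnegative
  ok <- matrix(0.1, 2, 2)
  expect_equal(repair_negative_nu(ok, "CTP", raw_nu = ok), ok)
  # no observed raw nu in an affected cell type: error
  raw_bad <- matrix(c(NA, NA, 0.1, 0.1), 2, 2)
  expect_error(repair_negative_nu(matrix(c(-1, 0, 0, 0), 2, 2), "CTP",
                                  raw_nu = raw_bad),
               "cannot repair")
})
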