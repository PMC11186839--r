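test_that("aggregation computes pseudobulk means and noise variances", {
  # one pair with cells 1,2,3: mean 2, sample variance 1, nu = 1/3
  cg <- cell_gene(c(1, 2, 3), rep("i1", 3), rep("c1", 3))
  pb <- aggregate_cells(cg)
  expect_equal(pb$y[1, 1], 2)
  expect_equal(pb$nu[1, 1], 1 / 3)

  # constant cells: zero variance
  pb2 <- aggregate_cells(cell_gene(rep(5, 4), rep("i1", 4), rep("c1", 4)))
  expect_equal(pb2$y[1, 1], 5)
  expect_equal(pb2$nu[1, 1], 0)

  # two cell types, 2 cells each, sigma2 = 4 in both: nu_op = 2*(2/16)*4 = 1
  v <- c(1 - sqrt(2), 1 + sqrt(2))
  cg3 <- cell_gene(c(v, 5 + v), rep("i1", 4), rep(c("a", "b"), each = 2))
  pb3 <- aggregate_cells(cg3)
  expect_equal(unname(pb3$nu[1, ]), c(2, 2))     # sigma2/n = 4/2
  expect_equal(unname(pb3$nu_op[1]), 1)
  expect_equal(unname(pb3$P[1, ]), c(0.5, 0.5))
})

test_that("single-cell pairs are missing and empty genes error", {
  cg <- cell_gene(c(1, 2, 3), c("i1", "i1", "i1"), c("a", "a", "b"))
  pb <- aggregate_cells(cg)
  expect_true(is.na(pb$y[1, "b"]))   # n = 1: variance undefined
  expect_true(is.na(pb$nu[1, "b"]))
  expect_error(cell_gene(numeric(0), character(0), character(0)), "empty")
})

test_that("technical replicates keep the copy with the most cells", {
  cg <- cell_gene(c(1, 2, 3, 10, 20),
                  c("i1:r1", "i1:r1", "i1:r1", "i1:r2", "i1:r2"),
                  rep("a", 5))
  pb <- aggregate_cells(cg, keep_largest_replicate = TRUE)
  expect_equal(nrow(pb$y), 1L)
  expect_equal(unname(pb$y[1, 1]), 2)  # r1 (3 cells) wins over r2 (2 cells)
})

test_that("missingness rules: cell-count threshold and individual filter", {
  set.seed(2)
  vals <- rnorm(11 + 10)
  pb <- aggregate_cells(cell_gene(vals, rep("i1", 21),
                                  rep(c("a", "b"), c(11, 10))))
  out <- apply_missingness(pb, min_cells = 10, min_cells_per_individual = 10)
  # n = 11 kept, n = 10 masked ("no more than ten cells" rule)
  expect_false(out$mask[1, "a"])
  expect_true(out$mask[1, "b"])
  # individual with 99 total cells dropped under the default 100-cell rule
  vals2 <- rnorm(120 + 99)
  ind2 <- rep(c("j1", "j2"), c(120, 99))
  ct2 <- c(rep(c("a", "b"), 60), rep(c("a", "b"), length.out = 99))
  pb2 <- aggregate_cells(cell_gene(vals2, ind2, ct2))
  out2 <- apply_missingness(pb2, min_cells = 10, min_cells_per_individual = 100)
  expect_false("j2" %in% out2$individuals)
  expect_true("j1" %in% out2$individuals)
  # all entries above threshold: no mask
  pb_ok <- random_pb(5, 3)
  expect_true(all(!apply_missingness(pb_ok, 10, 1)$mask))
  expect_error(apply_missingness(pb2, min_cells_per_individual = 1e6),
               "all individuals")
})

test_that("standardization centers and scales on the OP, and is invertible", {
  y <- rbind(c(0, 0), c(2, 2))
  nu <- matrix(0.5, 2, 2)
  pb <- as_pseudobulk(y, nu)
  s <- standardize_pseudobulk(pb)
  expect_equal(unname(s$y_op), c(-1, 1) / sqrt(2))  # (0,2) shifted/scaled
  expect_equal(mean(s$y_op), 0)
  expect_equal(var(s$y_op), 1)
  expect_equal(s$scale_record$scale, sqrt(2))  # sample sd of (0, 2)
  expect_equal(unname(s$nu[1, 1]), 0.25)       # nu / OP variance
  # idempotence on already standardized data
  s2 <- standardize_pseudobulk(s)
  expect_equal(s2$y, s$y)
  # round trip
  back <- unstandardize_pseudobulk(s)
  expect_equal(back$y, pb$y)
  expect_equal(back$nu, pb$nu)
  # constant OP errors
  expect_error(standardize_pseudobulk(as_pseudobulk(matrix(1, 3, 2),
                                                    matrix(.1, 3, 2))),
               "constant")
})

test_that("OP reconstruction: proportion-weighted CTP equals OP", {
  set.seed(9)
  vals <- rnorm(400)
  ind <- rep(paste0("i", 1:4), each = 100)
  ct <- unlist(lapply(1:4, function(i) sample(rep(c("a", "b", "c"),
                                                  length.out = 100))))
  pb <- aggregate_cells(cell_gene(vals, ind, ct))
  expect_equal(rowSums(pb$P * pb$y), pb$y_op, tolerance = 1e-12)
})

test_that("sigma2 estimator is unbiased for non-Gaussian cells", {
  # 10,000 pairs of n = 5 exponential cells (true variance 1)
  set.seed(31)
  n_pairs <- 10000; n_cells <- 5
  x <- matrix(rexp(n_pairs * n_cells), n_pairs, n_cells)
  s2 <- apply(x, 1, var)
  mc_se <- sd(s2) / sqrt(n_pairs)
  expect_lt(abs(mean(s2) - 1), 3 * mc_se)
})
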