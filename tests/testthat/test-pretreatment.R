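test_that("variance filter drops constant columns and only those", {
  withr::with_seed(1, {
    X <- cbind(A = rnorm(10), B = rep(2, 10), C = rnorm(10))
  })
  ds <- qsar_dataset(sprintf("c%d", 1:10), X, rnorm(10))
  res <- remove_low_variance(ds, 0)
  expect_identical(colnames(res$dataset$X), c("A", "C"))
  expect_identical(res$log$dropped_constant, "B")
  # variance_tol = 0 with no constant columns: identity
  res2 <- remove_low_variance(res$dataset, 0)
  expect_identical(res2$dataset$X, res$dataset$X)
  # all-removed is an error
  ds3 <- qsar_dataset(c("a", "b"), cbind(K = c(1, 1)), c(1, 2))
  expect_error(remove_low_variance(ds3, 0), "all 1 descriptors")
})

test_that("correlation filter removes near-duplicates, keeps the rest", {
  withr::with_seed(11, {
    a <- rnorm(40)
    X <- cbind(A = a, B = a + rnorm(40, sd = 0.01), C = rnorm(40),
               D = rnorm(40))
    y <- a + rnorm(40, sd = 0.3)
  })
  ds <- qsar_dataset(sprintf("c%d", 1:40), X, y)
  res <- correlation_filter(ds, 0.95)
  expect_equal(ncol(res$dataset$X), 3)
  expect_equal(nrow(res$log$dropped_correlated), 1)
  expect_true(res$log$dropped_correlated$abs_r > 0.95)
  # matches the brute-force maximal retained subset in size
  oracle <- brute_force_max_subset(X, 0.95)
  expect_equal(ncol(res$dataset$X), length(oracle))
  # threshold 1.0 with no exact duplicates: identity
  res2 <- correlation_filter(ds, 1.0)
  expect_identical(colnames(res2$dataset$X), colnames(X))
  # exact duplicate: one of the two goes
  ds3 <- qsar_dataset(sprintf("c%d", 1:40), cbind(A = a, B = a), y)
  expect_equal(ncol(correlation_filter(ds3, 0.99)$dataset$X), 1)
})

test_that("correlation filter is idempotent and deterministic", {
  gen <- generate_dataset(synthetic_spec(n_descriptors = 60,
                                         block_correlation = 0.97,
                                         n_near_constant = 0, seed = 9))
  r1 <- correlation_filter(gen$dataset, 0.95)
  r2 <- correlation_filter(r1$dataset, 0.95)
  expect_identical(colnames(r2$dataset$X), colnames(r1$dataset$X))
  expect_equal(nrow(r2$log$dropped_correlated), 0)
  r3 <- correlation_filter(gen$dataset, 0.95)
  expect_identical(r3$log$dropped_correlated, r1$log$dropped_correlated)
})

test_that("normalization variants evaluate the stated formulas", {
  ds <- qsar_dataset(c("a", "b", "c"), cbind(K = c(0, 5, 10)), c(1, 2, 3))
  paper <- apply_normalizer(ds, fit_normalizer(ds, "paper"))
  expect_num_equal(unname(paper$X[, 1]), c(-1, -0.5, 0))
  mm <- apply_normalizer(ds, fit_normalizer(ds, "minmax"))
  expect_num_equal(unname(mm$X[, 1]), c(0, 0.5, 1))
  # algebraic identity: paper + 1 == minmax, on arbitrary columns
  ds2 <- toy_dataset(n = 15, k = 4, noise_sd = 1, seed = 2)
  p2 <- apply_normalizer(ds2, fit_normalizer(ds2, "paper"))
  m2 <- apply_normalizer(ds2, fit_normalizer(ds2, "minmax"))
  expect_num_equal(p2$X + 1, m2$X)
})

test_that("normalizer refuses constant columns and unknown columns", {
  ds <- qsar_dataset(c("a", "b"), cbind(K = c(3, 3), L = c(1, 2)), c(1, 2))
  expect_error(fit_normalizer(ds), "constant column\\(s\\).*K")
  ds2 <- toy_dataset(n = 5, k = 2)
  params <- fit_normalizer(ds_subset(ds2, cols = "T1"))
  expect_error(apply_normalizer(ds2, params), "no normalization.*T2")
})

test_that("test-set values are transformed with training parameters, unclipped", {
  tr <- qsar_dataset(c("a", "b", "c"), cbind(K = c(0, 5, 10)), c(1, 2, 3))
  te <- qsar_dataset("z", cbind(K = 20), 4)
  params <- fit_normalizer(tr, "minmax")
  expect_num_equal(unname(apply_normalizer(te, params)$X[, 1]), 2)  # outside [0,1]
})

test_that("downstream statistics are invariant to the normalization variant", {
  ds <- toy_dataset(n = 20, k = 3, noise_sd = 0.5, seed = 8)
  p <- apply_normalizer(ds, fit_normalizer(ds, "paper"))
  m <- apply_normalizer(ds, fit_normalizer(ds, "minmax"))
  fp <- fit_mlr(p$X, p$y); fm <- fit_mlr(m$X, m$y)
  expect_num_equal(fp$r2, fm$r2)
  expect_num_equal(unname(fp$coefficients), unname(fm$coefficients))
  expect_num_equal(q2_loo(p$X, p$y), q2_loo(m$X, m$y))
  expect_num_equal(pearson_matrix(p$X), pearson_matrix(m$X))
})
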