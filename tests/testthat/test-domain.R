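test_that("leverages: trace, closed form, and query consistency", {
  ds <- toy_dataset(n = 15, k = 4, noise_sd = 0.3, seed = 23)
  h <- leverage_values(ds$X)
  expect_num_equal(sum(h), 4 + 1)
  expect_num_equal(mean(h), 5 / 15)
  # single centered descriptor closed form on [1..5]
  x <- cbind(d = c(1, 2, 3, 4, 5))
  expect_num_equal(leverage_values(x),
                   1 / 5 + (c(1:5) - 3)^2 / sum((c(1:5) - 3)^2))
  # a query equal to a training row has that row's leverage
  expect_num_equal(leverage_values(ds$X, ds$X[3, , drop = FALSE]), h[3])
  # affine rescaling of columns leaves leverage unchanged
  Xs <- sweep(sweep(ds$X, 2, c(2, -3, 10, 0.5), "*"), 2, c(1, 0, -4, 2), "+")
  expect_num_equal(leverage_values(Xs), h)
  expect_error(leverage_values(cbind(a = 1:6, b = 2 * (1:6))), "singular")
})

test_that("warning leverage implements both conventions", {
  expect_num_equal(warning_leverage(6, 36), 3 * 7 / 36)
  expect_num_equal(warning_leverage(6, 36, "p_only"), 0.5)
  expect_num_equal(warning_leverage(6, 72), warning_leverage(6, 36) / 2)
})

test_that("standardized residuals follow the stated scale", {
  expect_num_equal(standardized_residuals(c(1, 2), c(1, 2), dof = 1),
                   c(0, 0))
  # residuals (1, -1) with dof 1: s = sqrt(2), giving +/- 1/sqrt(2)
  expect_num_equal(standardized_residuals(c(1, 0), c(0, 1), dof = 1),
                   c(1, -1) / sqrt(2))
  # scale invariance
  y <- c(1, 2, 4, 8); yh <- c(1.2, 1.9, 4.4, 7.6)
  expect_num_equal(standardized_residuals(10 * y, 10 * yh, dof = 2),
                   standardized_residuals(y, yh, dof = 2))
  expect_error(standardized_residuals(c(1, 2), c(1, 3), dof = 1, s = 0),
               "zero residual scale")
})

test_that("williams_table flags constructed outliers and only those", {
  gen <- generate_dataset(synthetic_spec(n_descriptors = 40,
                                         n_near_constant = 0, seed = 26))
  sup <- attr(gen$truth, "support")
  tr <- ds_subset(gen$dataset, rows = 1:36)
  te <- ds_subset(gen$dataset, rows = 37:50)
  m <- fit_mlr(tr$X[, sup], tr$y)
  ad <- williams_table(m, tr, te)
  expect_num_equal(sum(ad$table$leverage[ad$table$partition == "train"]),
                   length(sup) + 1)
  expect_identical(ad$h_star, warning_leverage(length(sup), 36))
  expect_true(all(ad$table$flag %in%
    c("in_domain", "response_outlier", "structural_outlier", "both")))

  # a query 100 SDs outside the training cloud is a structural outlier
  far <- te
  far$X[1, ] <- far$X[1, ] + 100
  ad_far <- williams_table(m, tr, far)
  far_row <- ad_far$table[ad_far$table$compound == far$ids[1], ]
  expect_gt(far_row$leverage, ad_far$h_star)
  expect_true(far_row$flag %in% c("structural_outlier", "both"))

  # a +10s corrupted response is a response outlier
  bad <- te
  s <- sqrt(sum((tr$y - predict(m, tr$X))^2) / (36 - length(sup) - 1))
  bad$y[2] <- bad$y[2] + 10 * s
  ad_bad <- williams_table(m, tr, bad)
  bad_row <- ad_bad$table[ad_bad$table$compound == bad$ids[2], ]
  expect_gt(abs(bad_row$std_residual), 3)
  expect_true(bad_row$flag %in% c("response_outlier", "both"))
})

test_that("noise-free models yield zero outliers", {
  gen <- generate_dataset(synthetic_spec(noise_sd = 0, n_descriptors = 40,
                                         n_near_constant = 0, seed = 27))
  sup <- attr(gen$truth, "support")
  tr <- ds_subset(gen$dataset, rows = 1:36)
  te <- ds_subset(gen$dataset, rows = 37:50)
  m <- fit_mlr(tr$X[, sup], tr$y)
  ad <- williams_table(m, tr, te)
  expect_equal(sum(ad$table$flag == "response_outlier" |
                     ad$table$flag == "both"), 0)
  expect_num_equal(ad$table$std_residual, rep(0, 50))
})

test_that("the Williams plot renders", {
  ds <- toy_dataset(n = 12, k = 2, noise_sd = 0.4, seed = 28)
  m <- fit_mlr(ds$X, ds$y)
  ad <- williams_table(m, ds)
  path <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(path)
  expect_no_error(plot(ad))
  grDevices::dev.off()
  expect_true(file.size(path) > 0)
})
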