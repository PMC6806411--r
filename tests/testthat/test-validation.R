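test_that("r_squared and adjusted_r2 evaluate their formulas", {
  y <- c(1, 2, 3, 5)
  expect_num_equal(r_squared(y, y), 1)
  expect_num_equal(r_squared(y, rep(mean(y), 4)), 0)
  yhat <- c(1.1, 2.2, 2.9, 4.6)
  expect_num_equal(r_squared(y, yhat),
                   1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  expect_error(r_squared(rep(2, 4), yhat), "constant")
  expect_num_equal(adjusted_r2(0.9, 20, 0), 0.9)
  expect_num_equal(adjusted_r2(1, 20, 5), 1)
  expect_error(adjusted_r2(0.9, 7, 6), "n > p")
})

test_that("q2_loo: hand case, PRESS identity, exact limit", {
  # intercept-only on y = (0,1,2): LOO predictions (1.5, 1, 0.5)
  y <- c(0, 1, 2)
  expect_num_equal(q2_loo(NULL, y, method = "refit"), 1 - 4.5 / 2)
  expect_num_equal(q2_loo(NULL, y, method = "press"), 1 - 4.5 / 2)
  # PRESS shortcut == explicit refits on random data
  for (s in 1:4) {
    ds <- toy_dataset(n = 14, k = 3, noise_sd = 0.7, seed = 50 + s)
    expect_num_equal(q2_loo(ds$X, ds$y, "press"),
                     q2_loo(ds$X, ds$y, "refit"), tol = 1e-10)
  }
  # noise-free exact linear data
  ds0 <- toy_dataset(n = 10, k = 2, noise_sd = 0)
  expect_num_equal(q2_loo(ds0$X, ds0$y), 1, tol = 1e-9)
  # Q2 <= R2 on noisy data (strict in practice)
  dsn <- toy_dataset(n = 16, k = 3, noise_sd = 1, seed = 77)
  expect_lt(q2_loo(dsn$X, dsn$y), fit_mlr(dsn$X, dsn$y)$r2)
})

test_that("r2_external distinguishes its two denominators", {
  ds <- toy_dataset(n = 10, k = 2, noise_sd = 0.3, seed = 31)
  m <- fit_mlr(ds$X, ds$y)
  te <- toy_dataset(n = 5, k = 2, noise_sd = 0.3, seed = 32)
  expect_num_equal(r2_external(m, te$X, predict(m, te$X), mean(ds$y)), 1)
  expect_num_equal(
    r2_external(m, te$X, predict(m, te$X), mean(ds$y), "as_printed"), 1)
  # brute-force evaluation of each variant on a 5-point case
  yhat <- predict(m, te$X)
  expect_num_equal(r2_external(m, te$X, te$y, mean(ds$y)),
                   1 - sum((yhat - te$y)^2) / sum((te$y - mean(ds$y))^2))
  expect_num_equal(r2_external(m, te$X, te$y, mean(ds$y), "as_printed"),
                   1 - sum((yhat - te$y)^2) / sum((yhat - mean(ds$y))^2))
  # all predictions at the training mean: standard 0 / as_printed error
  flat <- new_flat_model <- fit_mlr(cbind(x = c(1, 2, 3, 4)), rep(2, 4))
  expect_num_equal(
    r2_external(flat, cbind(x = c(0, 5)), c(1, 3), y_train_mean = 2),
    1 - sum((2 - c(1, 3))^2) / sum((c(1, 3) - 2)^2))
  expect_error(
    r2_external(flat, cbind(x = c(0, 5)), c(1, 3), 2, "as_printed"),
    "zero denominator")
})

test_that("standardized contributions reproduce the printed table", {
  # recomputation from the printed standardized coefficients
  b <- c(0.513, 0.500, 0.631, 0.383, -1.061, 0.756)
  pct <- 100 * abs(b) / sum(abs(b))
  expect_equal(round(pct, 1), c(13.3, 13.0, 16.4, 10.0, 27.6, 19.7))
  # function-level checks on constructed data
  ds <- toy_dataset(n = 20, k = 3, noise_sd = 0.2, seed = 12)
  m <- fit_mlr(ds$X, ds$y)
  con <- standardized_contributions(m, ds$X, ds$y)
  expect_num_equal(sum(con$percent), 100)
  expect_num_equal(con$std_coef,
                   unname(apply(ds$X, 2, sd) * m$coefficients / sd(ds$y)))
  # sj = Sy and bj = 1 gives bj* = 1
  X1 <- cbind(a = c(-1, 0, 1, 2))
  y1 <- c(0, 1, 2, 3)  # slope 1, sd(y) == sd(a)
  expect_num_equal(
    standardized_contributions(fit_mlr(X1, y1), X1, y1)$std_coef, 1)
})

test_that("pearson_matrix matches the covariance-formula oracle", {
  withr::with_seed(14, X <- matrix(rnorm(30), 10, 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  P <- pearson_matrix(X)
  brute <- function(u, v) {
    cu <- u - mean(u); cv <- v - mean(v)
    sum(cu * cv) / sqrt(sum(cu^2) * sum(cv^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_num_equal(P[i, j], brute(X[, i], X[, j]), tol = 1e-12)
  expect_num_equal(pearson_matrix(cbind(a = X[, 1], b = X[, 1]))[1, 2], 1)
  expect_num_equal(pearson_matrix(cbind(a = X[, 1], b = -X[, 1]))[1, 2], -1)
  expect_error(pearson_matrix(cbind(a = X[, 1], b = rep(1, 10))),
               "constant")
})

test_that("vif: closed form, regression oracle, error cases", {
  # two descriptors at r = 0.6377: both VIF = 1/(1 - r^2)
  R <- matrix(c(1, 0.6377, 0.6377, 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_num_equal(unname(vif(R)), rep(1 / (1 - 0.6377^2), 2), tol = 1e-6)
  # orthogonal descriptors: VIF 1
  expect_num_equal(unname(vif(diag(3))), rep(1, 3))
  # inverse-correlation diagonal == 1/(1 - R2) from explicit regressions
  withr::with_seed(15, {
    Z <- matrix(rnorm(120), 30, 4)
    Z[, 2] <- Z[, 1] * 0.8 + rnorm(30, sd = 0.5)
    colnames(Z) <- paste0("v", 1:4)
  })
  v1 <- vif(Z)
  v2 <- vapply(1:4, function(i) {
    r2 <- summary(lm(Z[, i] ~ Z[, -i]))$r.squared
    1 / (1 - r2)
  }, 0)
  expect_num_equal(unname(v1), v2, tol = 1e-8)
  expect_error(vif(matrix(c(1, 1, 1, 1), 2)), "singular")
})

test_that("coefficient inference matches the textbook formulas", {
  withr::with_seed(16, {
    x <- rnorm(15); y <- 2 + 3 * x + rnorm(15, sd = 0.4)
  })
  X <- cbind(d = x)
  m <- fit_mlr(X, y)
  inf <- coefficient_inference(m, X, y)
  s <- summary(lm(y ~ x))
  expect_num_equal(inf$estimate, unname(coef(s)[, 1]), tol = 1e-10)
  expect_num_equal(inf$se, unname(coef(s)[, 2]), tol = 1e-10)
  expect_num_equal(inf$t, unname(coef(s)[, 3]), tol = 1e-8)
  expect_num_equal(inf$p, unname(coef(s)[, 4]), tol = 1e-8)
  # exact fit: unbounded t, flagged
  Xe <- cbind(d = c(0, 1, 2, 3))
  me <- fit_mlr(Xe, c(1, 3, 5, 7))
  infe <- coefficient_inference(me, Xe, c(1, 3, 5, 7))
  expect_true(attr(infe, "exact_fit"))
  expect_true(all(is.infinite(infe$t[infe$estimate != 0])))
})

test_that("null-descriptor p-values are uniform (type-I error)", {
  # 10000 replicates keep the Monte-Carlo SE (~0.2%) well inside the
  # 4.5-5.5% acceptance band
  hits <- withr::with_seed(4242, {
    vapply(seq_len(10000), function(i) {
      x <- rnorm(12); y <- rnorm(12)
      X <- cbind(d = x)
      coefficient_inference(fit_mlr(X, y), X, y)$p[2] < 0.05
    }, NA)
  })
  expect_gt(mean(hits), 0.045)
  expect_lt(mean(hits), 0.055)
})

test_that("crp2 evaluates the chance-correlation statistic", {
  # printed originals reproduce the printed 0.8439 within rounding
  expect_equal(crp2(0.9545, 0.3599, r2_original = 0.9111), 0.8439,
               tolerance = 1e-4)
  expect_equal(crp2(0.9545, 0.3599), 0.8439, tolerance = 1e-4)
  expect_num_equal(crp2(0.8, 0), 0.64)       # Rr = 0 gives R^2
  expect_num_equal(crp2(0.7, 0.7), 0)        # R == Rr gives 0
  expect_error(crp2(0.3, 0.5), "better than the original")
})

test_that("y_randomization separates signal from scrambled response", {
  ds <- toy_dataset(n = 30, k = 4, noise_sd = 0.15, seed = 18)
  yr <- y_randomization(ds$X, ds$y, n_iterations = 10, seed = 7)
  expect_equal(nrow(yr$iterations), 10)
  expect_gt(yr$original[["R2"]], 0.9)
  expect_lt(yr$average_r2, 0.3)
  expect_gt(yr$crp2, 0.5)
  expect_num_equal(yr$average_r, mean(yr$iterations$R))
  # reproducibility from seed
  yr2 <- y_randomization(ds$X, ds$y, n_iterations = 10, seed = 7)
  expect_identical(yr$iterations, yr2$iterations)
  expect_error(y_randomization(ds$X, ds$y, n_iterations = 0, seed = 1),
               ">= 1")
  expect_error(y_randomization(ds$X, ds$y, 10), "seed")
})

test_that("the printed Y-randomization table is internally consistent", {
  fx <- published_model_fixture()
  t5 <- fx$table5
  # agreement to the 4-dp printed precision (+/- 1.5 print ulp: the table
  # was computed from unrounded inputs)
  expect_lt(abs(mean(t5$random$R) - t5$average_r), 1.5e-4)
  expect_lt(abs(mean(t5$random$R2) - t5$average_r2), 1.5e-4)
  expect_lt(abs(mean(t5$random$Q2) - t5$average_q2), 1.5e-4)
  expect_lt(abs(crp2(t5$original[["R"]], mean(t5$random$R),
                     r2_original = t5$original[["R2"]]) - t5$crp2),
            1.5e-4)
})

test_that("validate_model + acceptance_checklist wire the battery together", {
  ds <- toy_dataset(n = 24, k = 3, noise_sd = 0.2, seed = 19)
  te <- toy_dataset(n = 8, k = 3, noise_sd = 0.2, seed = 20)
  m <- fit_mlr(ds$X, ds$y)
  rep <- validate_model(m, ds, te)
  expect_num_equal(rep$r2, m$r2)
  expect_num_equal(rep$r2_adjusted, adjusted_r2(m$r2, 24, 3))
  expect_num_equal(rep$q2_loo, q2_loo(ds$X, ds$y))
  expect_lte(rep$q2_loo, rep$r2)
  expect_num_equal(sum(rep$contributions$percent), 100)
  expect_true(all(rep$vif >= 1))
  yr <- y_randomization(ds$X, ds$y, 10, seed = 3)
  chk <- acceptance_checklist(rep, yr)
  expect_s3_class(chk, "qsar_checklist")
  expect_equal(nrow(chk), 9)
  expect_true(attr(chk, "overall"))
  # a failing criterion flips the verdict
  rep_bad <- rep; rep_bad$r2 <- 0.5
  chk_bad <- acceptance_checklist(rep_bad, yr)
  expect_false(chk_bad$pass[chk_bad$criterion == "R2 >= 0.6"])
  expect_false(attr(chk_bad, "overall"))
  # R2 - Q2 > 0.3 fails the difference rule
  rep_gap <- rep; rep_gap$r2 <- 0.95; rep_gap$q2_loo <- 0.55
  chk_gap <- acceptance_checklist(rep_gap, yr)
  expect_false(chk_gap$pass[chk_gap$criterion == "R2 - Q2 <= 0.3"])
  # missing field: not evaluable, overall fail
  chk_na <- acceptance_checklist(rep, NULL)
  expect_true(is.na(chk_na$pass[chk_na$criterion == "cRp2 > 0.5"]))
  expect_false(attr(chk_na, "overall"))
})

test_that("the paper's printed validation values satisfy the checklist", {
  rep <- list(r2 = 0.911, q2_loo = 0.870, r2_test = 0.5850,
              r2_adjusted = 0.893, n_test = 14,
              vif = c(1.5021, 1.4789, 1.4376, 1.4177, 4.5022, 4.3800),
              coefficients = data.frame(
                term = c("(Intercept)", paste0("d", 1:6)),
                t = c(1, 7.5604, 7.4649, 9.4970, 5.8502, -9.5663, 6.7912)))
  chk <- acceptance_checklist(rep, list(crp2 = 0.840))
  expect_true(attr(chk, "overall"))
})
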