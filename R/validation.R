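# The statistical validation battery: fit statistics, leave-one-out Q2,
# external R2, Y-randomization with cRp2, standardized contributions,
# collinearity diagnostics, and the acceptance checklist.

#' Coefficient of determination
#'
#' `R2 = 1 - SSE/SStot` of predictions `yhat` against observations `y`.
#'
#' @param y,yhat numeric vectors of equal length >= 2; `y` non-constant.
#' @return A single double.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop_named("r_squared: y is constant")
  1 - sum((y - yhat)^2) / sst
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R2)(n - 1)/(n - p - 1)`.
#'
#' @param r2 unadjusted R2.
#' @param n number of observations.
#' @param p number of predictors.
#' @return A single double.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop_named("adjusted_r2 requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Leave-one-out cross-validated Q2
#'
#' For each training compound the model is refitted without it and used to
#' predict it; `Q2 = 1 - PRESS / sum((y - mean(y))^2)`, the mean taken over
#' the full training activity vector. The default `"press"` method uses
#' the algebraic identity `e_i / (1 - h_ii)` for the deleted residuals;
#' `"refit"` performs the n explicit refits (the two agree to solver
#' precision, a property the test suite asserts).
#'
#' @param X descriptor matrix of the model's columns (may have 0 columns
#'   for an intercept-only model).
#' @param y activity vector.
#' @param method `"press"` (hat-matrix shortcut) or `"refit"`.
#' @return A single double (can be negative: worse than the mean).
#' @export
q2_loo <- function(X, y, method = c("press", "refit")) {
  method <- match.arg(method)
  if (is.null(X)) X <- matrix(numeric(0), length(y), 0L)
  if (is.null(dim(X))) X <- cbind(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n < p + 3L) stop_named("q2_loo requires n >= p + 3")
  Xd <- cbind(1, X)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop_named("q2_loo: y is constant")
  if (method == "press") {
    qd <- qr(Xd)
    if (qd$rank < ncol(Xd)) stop_named("q2_loo: rank-deficient design")
    e <- qr.resid(qd, y)
    h <- rowSums(qr.Q(qd)[, seq_len(qd$rank), drop = FALSE]^2)
    press <- sum((e / (1 - h))^2)
  } else {
    pred <- vapply(seq_len(n), function(i) {
      fit <- tryCatch(.lm.fit(Xd[-i, , drop = FALSE], y[-i]),
                      error = function(err)
                        stop_named("q2_loo: subfit without row %d failed", i))
      if (any(abs(fit$coefficients) > 1e12) ||
          fit$rank < ncol(Xd))
        stop_named("q2_loo: subfit without row %d is rank-deficient", i)
      drop(Xd[i, ] %*% fit$coefficients)
    }, 0)
    press <- sum((y - pred)^2)
  }
  1 - press / sst
}

#' External (test-set) R2
#'
#' Predictive squared correlation on held-out compounds. The `"standard"`
#' variant uses `1 - sum((yhat - y_test)^2) / sum((y_test - ybar_train)^2)`;
#' `"as_printed"` replaces the denominator by
#' `sum((yhat - ybar_train)^2)`, the literal reading of some published
#' formulations (degenerate when all predictions equal the training mean).
#'
#' @param model an `mlr_model`.
#' @param X_test,y_test test descriptors and activities.
#' @param y_train_mean mean of the training activities.
#' @param variant `"standard"` (default) or `"as_printed"`.
#' @return A single double.
#' @export
r2_external <- function(model, X_test, y_test, y_train_mean,
                        variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  if (inherits(X_test, "qsar_dataset")) X_test <- X_test$X
  stopifnot(nrow(X_test) == length(y_test), length(y_test) >= 1)
  yhat <- predict(model, X_test)
  denom <- if (variant == "standard") sum((y_test - y_train_mean)^2)
           else sum((yhat - y_train_mean)^2)
  if (denom == 0) stop_named("r2_external: zero denominator (%s variant)",
                             variant)
  1 - sum((yhat - y_test)^2) / denom
}

#' Standardized coefficients and contribution percentages
#'
#' The standardized coefficient of descriptor j is `bj* = s_j * b_j / S_y`
#' (descriptor SD times raw coefficient over activity SD); its percentage
#' contribution is `100 |bj*| / sum_k |bk*|`. Signs are kept on `bj*` so
#' the direction of influence is visible.
#'
#' @param model an `mlr_model`.
#' @param X_train,y_train the data the model was fitted on.
#' @return data.frame with columns `descriptor`, `std_coef`, `percent`
#'   (percent sums to 100).
#' @export
standardized_contributions <- function(model, X_train, y_train) {
  if (inherits(X_train, "qsar_dataset")) {
    y_train <- X_train$y; X_train <- X_train$X
  }
  nm <- names(model$coefficients)
  if (length(nm) == 0L) stop_named("model has no descriptors")
  sy <- stats::sd(y_train)
  if (sy == 0) stop_named("zero activity standard deviation")
  sj <- apply(X_train[, nm, drop = FALSE], 2L, stats::sd)
  bstar <- sj * model$coefficients / sy
  data.frame(descriptor = nm, std_coef = unname(bstar),
             percent = unname(100 * abs(bstar) / sum(abs(bstar))))
}

#' Pearson correlation matrix of descriptors
#'
#' @param X numeric matrix with >= 2 rows and non-constant columns.
#' @return Symmetric matrix with unit diagonal.
#' @export
pearson_matrix <- function(X) {
  if (inherits(X, "qsar_dataset")) X <- X$X
  stopifnot(nrow(X) >= 2)
  v <- apply(X, 2L, stats::var)
  if (any(v == 0))
    stop_named("constant column(s): %s",
               paste(colnames(X)[v == 0], collapse = ", "))
  stats::cor(X)
}

#' Variance inflation factors
#'
#' `VIF_i = 1 / (1 - R2_i)` where `R2_i` is from regressing descriptor i
#' on the others; computed as the diagonal of the inverse correlation
#' matrix. Accepts either a correlation matrix (symmetric, unit diagonal)
#' or a raw descriptor matrix.
#'
#' @param x correlation matrix or descriptor matrix (>= 2 columns).
#' @return Named vector of VIFs (all >= 1).
#' @export
vif <- function(x) {
  if (inherits(x, "qsar_dataset")) x <- x$X
  is_cor <- is.matrix(x) && nrow(x) == ncol(x) &&
    isSymmetric(unname(x), tol = 1e-8) &&
    all(abs(diag(x) - 1) < 1e-8) && all(abs(x) <= 1 + 1e-8)
  R <- if (is_cor) x else pearson_matrix(x)
  if (ncol(R) < 2L) stop_named("vif needs at least 2 descriptors")
  Rinv <- tryCatch(chol2inv(chol(R)), error = function(e)
    stop_named("correlation matrix is singular or not positive definite"))
  out <- diag(Rinv)
  names(out) <- colnames(R)
  out
}

#' Classical OLS coefficient inference
#'
#' Standard errors from `sigma2 * (X'X)^-1`, t = estimate/se, and
#' two-sided p from the t distribution with `n - p - 1` degrees of
#' freedom. A noise-free (exact) fit has zero residual variance; t is then
#' reported as `Inf` (sign of the estimate) with p = 0 and the result
#' carries attribute `"exact_fit" = TRUE`.
#'
#' @param model an `mlr_model`.
#' @param X_train,y_train the model's training data.
#' @return data.frame with columns `term`, `estimate`, `se`, `t`, `p`
#'   (intercept first).
#' @export
coefficient_inference <- function(model, X_train, y_train) {
  if (inherits(X_train, "qsar_dataset")) {
    y_train <- X_train$y; X_train <- X_train$X
  }
  nm <- names(model$coefficients)
  Xd <- cbind("(Intercept)" = 1, X_train[, nm, drop = FALSE])
  n <- nrow(Xd); k <- ncol(Xd)
  if (n <= k) stop_named("coefficient inference requires n > p + 1")
  qd <- qr(Xd)
  if (qd$rank < k) stop_named("rank-deficient design")
  est <- c(model$intercept, model$coefficients)
  resid <- y_train - drop(Xd %*% est)
  sigma2 <- sum(resid^2) / (n - k)
  XtXinv <- chol2inv(qr.R(qd))
  exact <- sigma2 < 1e-24
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  tval <- if (exact) ifelse(est == 0, 0, sign(est) * Inf) else est / se
  pval <- if (exact) ifelse(est == 0, 1, 0)
          else 2 * stats::pt(-abs(tval), df = n - k)
  out <- data.frame(term = colnames(Xd), estimate = unname(est),
                    se = unname(se), t = unname(tval), p = unname(pval))
  attr(out, "exact_fit") <- exact
  out
}

#' cRp2 chance-correlation statistic
#'
#' `cRp2 = R * sqrt(R2 - Rr^2)`, where R (and R2 = R^2 unless supplied)
#' belong to the original model and Rr is the average correlation
#' coefficient of the Y-randomized models. Values above 0.5 indicate the
#' original fit is not a chance correlation.
#'
#' @param r_original correlation coefficient of the original model.
#' @param rr_average average R over the randomized refits.
#' @param r2_original optional original R2 (defaults to `r_original^2`,
#'   useful when reproducing printed tables that round the two
#'   separately).
#' @return A single double.
#' @examples
#' crp2(0.9545, 0.3599)   # ~0.844
#' @export
crp2 <- function(r_original, rr_average, r2_original = r_original^2) {
  if (rr_average^2 > r2_original)
    stop_named("randomized models fit better than the original (Rr^2 > R2)")
  r_original * sqrt(r2_original - rr_average^2)
}

#' Y-randomization (response scrambling) test
#'
#' Repeatedly permutes the training activities, refits the *same*
#' descriptor subset, and records R (correlation of permuted response with
#' fit), R2 and leave-one-out Q2. A robust model shows near-zero averages
#' over the randomized fits and `cRp2 > 0.5`.
#'
#' @param X_train matrix restricted to the model's descriptors.
#' @param y_train training activities.
#' @param n_iterations number of permutations (default 10).
#' @param seed integer seed (required).
#' @return An object of class `yrand_result`: `iterations` (data.frame of
#'   R, R2, Q2 per permutation), `average_r`, `average_r2`, `average_q2`,
#'   `original` (named vector R, R2, Q2), `crp2`, `n_iterations`, `seed`.
#' @export
y_randomization <- function(X_train, y_train, n_iterations = 10, seed) {
  if (missing(seed)) stop_named("y_randomization: seed is required")
  if (inherits(X_train, "qsar_dataset")) {
    y_train <- X_train$y; X_train <- X_train$X
  }
  if (n_iterations < 1) stop_named("n_iterations must be >= 1")
  eval_fit <- function(yy) {
    m <- fit_mlr(X_train, yy)
    c(R = sqrt(max(m$r2, 0)), R2 = m$r2, Q2 = q2_loo(X_train, yy))
  }
  orig <- eval_fit(y_train)
  rows <- with_seed(seed, {
    t(vapply(seq_len(n_iterations), function(i) {
      yp <- sample(y_train)
      stopifnot(identical(sort(yp), sort(y_train)))  # same multiset
      eval_fit(yp)
    }, c(R = 0, R2 = 0, Q2 = 0)))
  })
  iterations <- data.frame(iteration = seq_len(n_iterations), rows)
  structure(list(iterations = iterations,
                 average_r = mean(rows[, "R"]),
                 average_r2 = mean(rows[, "R2"]),
                 average_q2 = mean(rows[, "Q2"]),
                 original = orig,
                 crp2 = crp2(orig[["R"]], mean(rows[, "R"])),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat(sprintf("<yrand_result> %d permutations: avg R = %.4f, avg R2 = %.4f, avg Q2 = %.4f\n",
              x$n_iterations, x$average_r, x$average_r2, x$average_q2))
  cat(sprintf("  original R = %.4f, R2 = %.4f, Q2 = %.4f; cRp2 = %.4f\n",
              x$original[["R"]], x$original[["R2"]], x$original[["Q2"]],
              x$crp2))
  invisible(x)
}

#' Full validation report for a fitted model
#'
#' Convenience wrapper assembling the whole battery: fit statistics,
#' adjusted R2, overall F, Q2(LOO), external R2 (when test data given),
#' per-coefficient inference, descriptor correlation matrix, VIFs and
#' standardized contributions.
#'
#' @param model an `mlr_model`.
#' @param train training [qsar_dataset()] (or list with `X`, `y`).
#' @param test optional test [qsar_dataset()].
#' @param r2_test_variant passed to [r2_external()].
#' @return An object of class `validation_report` (a named list).
#' @export
validate_model <- function(model, train, test = NULL,
                           r2_test_variant = "standard") {
  nm <- names(model$coefficients)
  Xtr <- train$X[, nm, drop = FALSE]; ytr <- train$y
  n <- nrow(Xtr); p <- length(nm)
  yhat <- predict(model, Xtr)
  r2 <- r_squared(ytr, yhat)
  sse <- sum((ytr - yhat)^2)
  f_stat <- if (sse > 0)
    ((sum((ytr - mean(ytr))^2) - sse) / p) / (sse / (n - p - 1)) else Inf
  rep <- list(
    r2 = r2,
    r2_adjusted = adjusted_r2(r2, n, p),
    see = sqrt(sse / (n - p - 1)),
    f_statistic = f_stat,
    q2_loo = q2_loo(Xtr, ytr),
    r2_test = if (!is.null(test))
      r2_external(model, test$X, test$y, mean(ytr),
                  variant = r2_test_variant) else NA_real_,
    n_train = n, n_test = if (!is.null(test)) length(test$y) else 0L,
    coefficients = coefficient_inference(model, Xtr, ytr),
    pearson_matrix = if (p >= 2) pearson_matrix(Xtr) else NULL,
    vif = if (p >= 2) vif(Xtr) else NULL,
    contributions = standardized_contributions(model, Xtr, ytr))
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> R2 = %.4f (adj %.4f), SEE = %.4f, F = %.2f\n",
              x$r2, x$r2_adjusted, x$see, x$f_statistic))
  cat(sprintf("  Q2(LOO) = %.4f; R2(test) = %s; n = %d/%d\n", x$q2_loo,
              ifelse(is.na(x$r2_test), "-", sprintf("%.4f", x$r2_test)),
              x$n_train, x$n_test))
  invisible(x)
}

#' Model-quality acceptance checklist
#'
#' The standard QSAR acceptance thresholds: R2 >= 0.6, Q2 > 0.5,
#' R2 - Q2 <= 0.3, external test size >= 5, R2(test) >= 0.5, cRp2 > 0.5,
#' adjusted R2 > 0.6, all VIF < 10, all descriptor |t| > 2. A missing
#' input makes its criterion "not evaluable" and fails the overall
#' verdict.
#'
#' @param report a [validate_model()] result.
#' @param yrand a [y_randomization()] result (or NULL).
#' @param n_test external test-set size (defaults to `report$n_test`).
#' @return data.frame of class `qsar_checklist` with columns `criterion`,
#'   `value`, `threshold`, `pass`; overall verdict in attribute
#'   `"overall"`.
#' @export
acceptance_checklist <- function(report, yrand = NULL,
                                 n_test = report$n_test) {
  val <- function(x) if (is.null(x) || length(x) == 0L || all(is.na(x)))
    NA_real_ else x
  vif_max <- if (is.null(report$vif) || !length(report$vif)) NA_real_
             else max(report$vif)
  t_min <- if (is.null(report$coefficients) ||
               nrow(report$coefficients) < 2L) NA_real_
           else min(abs(report$coefficients$t[-1L]))
  r2q2 <- if (is.null(report$r2) || is.null(report$q2_loo)) NA_real_
          else report$r2 - report$q2_loo
  rows <- list(
    c("R2 >= 0.6",            val(report$r2),          0.6,  1),
    c("Q2(LOO) > 0.5",        val(report$q2_loo),      0.5,  1),
    c("R2 - Q2 <= 0.3",       r2q2,                    0.3, -1),
    c("n_test >= 5",          val(n_test),             5,    1),
    c("R2(test) >= 0.5",      val(report$r2_test),     0.5,  1),
    c("cRp2 > 0.5",           val(yrand$crp2),         0.5,  1),
    c("adjusted R2 > 0.6",    val(report$r2_adjusted), 0.6,  1),
    c("max VIF < 10",         vif_max,                 10,  -1),
    c("min |t| > 2",          t_min,                   2,    1))
  df <- data.frame(
    criterion = vapply(rows, `[[`, "", 1L),
    value = as.numeric(vapply(rows, `[[`, "", 2L)),
    threshold = as.numeric(vapply(rows, `[[`, "", 3L)))
  dir <- as.numeric(vapply(rows, `[[`, "", 4L))
  df$pass <- ifelse(is.na(df$value), NA,
                    ifelse(dir > 0, df$value >= df$threshold - 1e-12,
                           df$value <= df$threshold + 1e-12))
  attr(df, "overall") <- !anyNA(df$pass) && all(df$pass)
  class(df) <- c("qsar_checklist", "data.frame")
  df
}

#' @export
print.qsar_checklist <- function(x, ...) {
  cat("<qsar_checklist>\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-18s %10s  %s\n", x$criterion[i],
                ifelse(is.na(x$value[i]), "-", sprintf("%.4f", x$value[i])),
                if (is.na(x$pass[i])) "not evaluable"
                else if (x$pass[i]) "pass" else "FAIL"))
  cat(sprintf("  overall: %s\n",
              if (attr(x, "overall")) "PASS" else "FAIL"))
  invisible(x)
}
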