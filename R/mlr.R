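# Ordinary least squares with an intercept, and the Friedman lack-of-fit
# score that the GFA search uses as fitness.

new_mlr_model <- function(intercept, coefficients, n_train,
                          sse = NA_real_, see = NA_real_, r2 = NA_real_) {
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 n_train = as.integer(n_train),
                 p = length(coefficients),
                 sse = sse, see = see, r2 = r2),
            class = "mlr_model")
}

#' Fit a multiple linear regression model
#'
#' Ordinary least squares with an intercept. Rank deficiency is an error
#' (no silent pseudo-inverse): the aliased columns are named so the caller
#' can fix the descriptor subset.
#'
#' @param X numeric matrix of descriptor values (columns named), or a
#'   [qsar_dataset()] (in which case `y` is taken from it).
#' @param y numeric response vector.
#' @param names optional descriptor names overriding `colnames(X)`.
#' @return An object of class `mlr_model`: intercept, named coefficient
#'   vector, `n_train`, `p`, and cached fit statistics `sse`,
#'   `see = sqrt(SSE/(n-p-1))`, `r2` (NA when `y` is constant).
#' @examples
#' m <- fit_mlr(cbind(x = 0:2), c(1, 3, 5))
#' m$coefficients   # x = 2
#' @export
fit_mlr <- function(X, y = NULL, names = NULL) {
  if (inherits(X, "qsar_dataset")) { y <- X$y; X <- X$X }
  if (is.null(dim(X))) X <- cbind(x = X)
  storage.mode(X) <- "double"
  if (!is.null(names)) colnames(X) <- names
  if (is.null(colnames(X)) && ncol(X) > 0L)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_named("length(y) != nrow(X)")
  if (n < p + 2L)
    stop_named("need at least p + 2 = %d rows, got %d", p + 2L, n)
  Xd <- cbind("(Intercept)" = 1, X)
  qd <- qr(Xd)
  if (qd$rank < ncol(Xd)) {
    aliased <- colnames(Xd)[qd$pivot[(qd$rank + 1L):ncol(Xd)]]
    stop_named("rank-deficient design; collinear column(s): %s",
               paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qd, y)
  fitted <- drop(Xd %*% beta)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  see <- sqrt(sse / (n - p - 1L))
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  new_mlr_model(beta[[1L]], beta[-1L], n, sse = sse, see = see, r2 = r2)
}

#' @export
print.mlr_model <- function(x, digits = 4, ...) {
  terms <- c(sprintf("%+.*f(%s)", digits, x$coefficients,
                     names(x$coefficients)),
             sprintf("%+.*f", digits, x$intercept))
  cat("<mlr_model> y =", paste(terms, collapse = " "), "\n")
  cat(sprintf("  n = %d, p = %d", x$n_train, x$p))
  if (!is.na(x$r2)) cat(sprintf(", R2 = %.4f, SEE = %.4f", x$r2, x$see))
  cat("\n")
  invisible(x)
}

#' Predict activities from a fitted model
#'
#' @param object an `mlr_model`.
#' @param newdata descriptor matrix (or [qsar_dataset()]) supplying every
#'   descriptor the model uses; extra columns are ignored.
#' @param ... unused.
#' @return Numeric vector of predicted activities.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "qsar_dataset")) newdata <- newdata$X
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
    dimnames = list(NULL, names(object$coefficients)))
  need <- names(object$coefficients)
  missing <- setdiff(need, colnames(newdata))
  if (length(missing))
    stop_named("newdata lacks descriptor column(s): %s",
               paste(missing, collapse = ", "))
  if (length(need) == 0L) return(rep(object$intercept, nrow(newdata)))
  drop(newdata[, need, drop = FALSE] %*% object$coefficients) +
    object$intercept
}

#' Friedman lack-of-fit score
#'
#' `LOF = (SSE/M) / (1 - (c + d*p)/M)^2`, the penalized error the GFA
#' search minimizes: training error inflated as the model grows relative to
#' the training-set size `M`. For purely linear models the number of basis
#' functions is `c = p + 1` (the linear terms plus the intercept). A
#' literal reading with SEE in the numerator is available via
#' `numerator = "see"`.
#'
#' @param sse training sum of squared errors.
#' @param M number of training samples.
#' @param p number of descriptors in the model.
#' @param c number of basis functions (default `p + 1`).
#' @param d smoothing parameter (default 0.5); larger `d` punishes size
#'   harder.
#' @param numerator `"sse_over_m"` (default) or `"see"`.
#' @return An object of class `lof_score`: list with `lof`, `sse`, `c`,
#'   `d`, `p`, `M`.
#' @examples
#' lof(sse = 2, M = 10, p = 0, c = 0, d = 0)$lof   # 0.2
#' @export
lof <- function(sse, M, p, c = p + 1, d = 0.5,
                numerator = c("sse_over_m", "see")) {
  numerator <- match.arg(numerator)
  stopifnot(sse >= 0, M >= 1, p >= 0, d >= 0)
  penalty <- (c + d * p) / M
  if (penalty >= 1)
    stop_named("LOF penalty (c + d*p)/M = %.3f >= 1: model too complex for M = %d",
               penalty, M)
  num <- if (numerator == "sse_over_m") sse / M
         else sqrt(sse / (M - p - 1L))
  structure(list(lof = num / (1 - penalty)^2, sse = sse,
                 c = c, d = d, p = p, M = M, numerator = numerator),
            class = "lof_score")
}

#' @export
print.lof_score <- function(x, ...) {
  cat(sprintf("<lof_score> LOF = %.6g (SSE = %.6g, M = %d, p = %d, c = %g, d = %g)\n",
              x$lof, x$sse, x$M, x$p, x$c, x$d))
  invisible(x)
}
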