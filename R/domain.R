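# Leverage-based applicability domain: hat values against the training
# design, the warning leverage h*, standardized residuals, and the
# Williams-plot table with outlier flags.

#' Leverage (hat) values against a training design
#'
#' `h_i = x_i (X'X)^-1 x_i'` for each query row, where X is the training
#' descriptor matrix with an intercept column appended internally.
#' Training leverages sum to `p + 1` (the hat-matrix trace), asserted on
#' every call.
#'
#' @param X_train training descriptor matrix (full column rank).
#' @param X_query rows to evaluate (default: the training matrix itself);
#'   must supply the same columns.
#' @return Numeric vector of leverages, one per query row.
#' @export
leverage_values <- function(X_train, X_query = X_train) {
  if (inherits(X_train, "qsar_dataset")) X_train <- X_train$X
  if (inherits(X_query, "qsar_dataset")) X_query <- X_query$X
  if (is.null(dim(X_query))) X_query <- matrix(X_query, nrow = 1)
  if (!is.null(colnames(X_train)) && !is.null(colnames(X_query)))
    X_query <- X_query[, colnames(X_train), drop = FALSE]
  Xd <- cbind(1, X_train)
  qd <- qr(Xd)
  if (qd$rank < ncol(Xd))
    stop_named("leverage_values: singular X'X (rank-deficient training design)")
  XtXinv <- chol2inv(qr.R(qd))
  Q <- cbind(1, X_query)
  h <- rowSums((Q %*% XtXinv) * Q)
  h_train <- rowSums((Xd %*% XtXinv) * Xd)
  stopifnot(abs(sum(h_train) - ncol(Xd)) < 1e-6)
  h
}

#' Warning leverage h*
#'
#' The cutoff above which a compound is structurally outside the model's
#' domain. Two published conventions: `"eq9"` (default) gives
#' `3(p + 1)/n`; `"p_only"` gives `3p/n`.
#'
#' @param p number of descriptors in the model.
#' @param n number of training compounds.
#' @param variant `"eq9"` or `"p_only"`.
#' @return A single double.
#' @examples
#' warning_leverage(6, 36)            # 0.5833
#' warning_leverage(6, 36, "p_only")  # 0.5
#' @export
warning_leverage <- function(p, n, variant = c("eq9", "p_only")) {
  variant <- match.arg(variant)
  stopifnot(n > 0, p >= 0)
  if (variant == "eq9") 3 * (p + 1) / n else 3 * p / n
}

#' Standardized residuals
#'
#' Residuals divided by the training root-mean-square error
#' `s = sqrt(SSE/dof)`. Pass `s` explicitly to standardize test-set
#' residuals by the training scale (no refitting).
#'
#' @param y,yhat observed and predicted activities.
#' @param dof residual degrees of freedom used for `s` (typically
#'   `n - p - 1`); ignored when `s` is supplied.
#' @param s optional residual scale overriding the internal computation.
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(y, yhat, dof, s = NULL) {
  stopifnot(length(y) == length(yhat))
  r <- y - yhat
  if (is.null(s)) {
    stopifnot(dof >= 1)
    s <- sqrt(sum(r^2) / dof)
  }
  if (s == 0) {
    if (all(r == 0)) return(r)
    stop_named("zero residual scale with nonzero residuals")
  }
  r / s
}

#' Williams-plot table (applicability domain)
#'
#' Combines leverages against the training design, the warning leverage,
#' and standardized residuals (test residuals standardized by the training
#' scale) into one table with an outlier flag per compound:
#' `response_outlier` iff |standardized residual| > 3, `structural_outlier`
#' iff leverage > h*, `both`, else `in_domain`.
#'
#' @param model a fitted `mlr_model`.
#' @param train training [qsar_dataset()].
#' @param test optional test [qsar_dataset()].
#' @param h_variant passed to [warning_leverage()].
#' @return An object of class `ad_result`: data.frame `table` (compound,
#'   partition, leverage, std_residual, flag) plus `h_star`, `residual_scale`.
#' @export
williams_table <- function(model, train, test = NULL,
                           h_variant = "eq9") {
  nm <- names(model$coefficients)
  Xtr <- train$X[, nm, drop = FALSE]
  n <- nrow(Xtr); p <- length(nm)
  h_star <- warning_leverage(p, n, h_variant)
  res_tr <- train$y - predict(model, Xtr)
  s <- sqrt(sum(res_tr^2) / (n - p - 1))
  # exact (noise-free) fits leave only rounding noise in the residuals;
  # standardizing by it would amplify numerical dust into fake outliers
  exact <- s < 1e-8 * max(stats::sd(train$y), .Machine$double.eps)
  std_of <- function(y, yhat) {
    if (exact) rep(0, length(y))
    else standardized_residuals(y, yhat, dof = n - p - 1, s = s)
  }
  lev <- leverage_values(Xtr)
  tab <- data.frame(compound = train$ids, partition = "train",
                    leverage = lev,
                    std_residual = std_of(train$y, predict(model, Xtr)))
  if (!is.null(test)) {
    Xte <- test$X[, nm, drop = FALSE]
    tab <- rbind(tab, data.frame(
      compound = test$ids, partition = "test",
      leverage = leverage_values(Xtr, Xte),
      std_residual = std_of(test$y, predict(model, Xte))))
  }
  resp <- abs(tab$std_residual) > 3
  stru <- tab$leverage > h_star
  tab$flag <- ifelse(resp & stru, "both",
                     ifelse(resp, "response_outlier",
                            ifelse(stru, "structural_outlier", "in_domain")))
  rownames(tab) <- NULL
  structure(list(table = tab, h_star = h_star, residual_scale = s,
                 p = p, n_train = n),
            class = "ad_result")
}

#' @export
print.ad_result <- function(x, ...) {
  n_out <- sum(x$table$flag != "in_domain")
  cat(sprintf("<ad_result> %d compounds, h* = %.4f, %d outlier(s)\n",
              nrow(x$table), x$h_star, n_out))
  if (n_out > 0) print(x$table[x$table$flag != "in_domain", ])
  invisible(x)
}

#' Williams plot
#'
#' Standardized residuals against leverage, with the warning-leverage
#' vertical line and the +/-3 residual boundaries.
#'
#' @param x an `ad_result`.
#' @param ... forwarded to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.ad_result <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$leverage, tab$std_residual,
                 pch = ifelse(tab$partition == "train", 19, 1),
                 xlab = "leverage", ylab = "standardized residual",
                 ylim = range(c(tab$std_residual, -3.5, 3.5)),
                 xlim = range(c(tab$leverage, 0, x$h_star * 1.1)), ...)
  graphics::abline(v = x$h_star, lty = 2)
  graphics::abline(h = c(-3, 3), lty = 3)
  graphics::legend("topright", legend = c("train", "test"),
                   pch = c(19, 1), bty = "n")
  invisible(x)
}
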