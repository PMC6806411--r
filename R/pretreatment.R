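# Descriptor pretreatment: variance filter, greedy correlation filter,
# and column normalization fitted on the training partition only.

new_pretreatment_log <- function(dropped_constant = character(0),
                                 dropped_correlated = NULL,
                                 thresholds = list()) {
  if (is.null(dropped_correlated))
    dropped_correlated <- data.frame(dropped = character(0),
                                     kept = character(0),
                                     abs_r = numeric(0))
  structure(list(dropped_constant = dropped_constant,
                 dropped_correlated = dropped_correlated,
                 thresholds = thresholds),
            class = "pretreatment_log")
}

#' @export
print.pretreatment_log <- function(x, ...) {
  cat(sprintf("<pretreatment_log> %d constant/low-variance, %d correlated dropped\n",
              length(x$dropped_constant), nrow(x$dropped_correlated)))
  invisible(x)
}

#' Remove constant and near-constant descriptors
#'
#' Drops every descriptor whose sample variance is `<= variance_tol`.
#' Constant-value columns carry no information and break normalization;
#' descriptor tools routinely emit many of them.
#'
#' @param dataset a [qsar_dataset()].
#' @param variance_tol non-negative variance threshold (default `1e-6`).
#' @return A list `(dataset, log)`: the filtered dataset and a
#'   `pretreatment_log` naming the dropped columns.
#' @export
remove_low_variance <- function(dataset, variance_tol = 1e-6) {
  stopifnot(inherits(dataset, "qsar_dataset"), variance_tol >= 0)
  v <- apply(dataset$X, 2L, stats::var)
  drop <- colnames(dataset$X)[v <= variance_tol]
  if (length(drop) == ncol(dataset$X))
    stop_named("all %d descriptors have variance <= %g", ncol(dataset$X),
               variance_tol)
  out <- if (length(drop)) ds_subset(dataset, cols = setdiff(colnames(dataset$X), drop))
         else dataset
  list(dataset = out,
       log = new_pretreatment_log(dropped_constant = drop,
                                  thresholds = list(variance_tol = variance_tol)))
}

#' Remove highly correlated descriptors
#'
#' Greedy pairwise de-redundancy: while any retained pair has
#' `|Pearson r| >= r_threshold`, take the worst pair and drop one member -
#' the one less correlated with the activity (default), or the one with
#' smaller variance when `use_activity_tiebreak = FALSE`. The elimination
#' order is deterministic (lowest column index wins remaining ties), and
#' the operation is idempotent. This reproduces the intent of
#' de-redundancy filters such as V-WSP without their geometry-based
#' sampling.
#'
#' @param dataset a [qsar_dataset()].
#' @param r_threshold correlation threshold in (0, 1]; default 0.95.
#' @param use_activity_tiebreak keep, within an offending pair, the
#'   descriptor more correlated with the activity (default TRUE).
#' @return A list `(dataset, log)`; the log records each (dropped, kept,
#'   |r|) decision in order.
#' @export
correlation_filter <- function(dataset, r_threshold = 0.95,
                               use_activity_tiebreak = TRUE) {
  stopifnot(inherits(dataset, "qsar_dataset"),
            r_threshold > 0, r_threshold <= 1)
  X <- dataset$X
  if (ncol(X) < 2L)
    return(list(dataset = dataset,
                log = new_pretreatment_log(
                  thresholds = list(r_threshold = r_threshold))))
  C <- abs(stats::cor(X))
  C[!is.finite(C)] <- 0   # constant columns: leave for the variance filter
  diag(C) <- 0
  ry <- abs(suppressWarnings(stats::cor(X, dataset$y)))[, 1L]
  ry[!is.finite(ry)] <- 0
  vx <- apply(X, 2L, stats::var)
  alive <- rep(TRUE, ncol(X))
  names(alive) <- colnames(X)
  decisions <- list()
  repeat {
    Ca <- C[alive, alive, drop = FALSE]
    if (all(Ca < r_threshold)) break
    idx <- which(Ca == max(Ca), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L])[1L], ]
    pair <- rownames(Ca)[c(idx[[1L]], idx[[2L]])]
    score <- if (use_activity_tiebreak) ry[pair] else vx[pair]
    # drop the lower-scoring member; on an exact score tie drop the later column
    drop_nm <- if (score[1L] < score[2L]) pair[1L]
               else if (score[2L] < score[1L]) pair[2L]
               else pair[2L]
    keep_nm <- setdiff(pair, drop_nm)
    decisions[[length(decisions) + 1L]] <-
      data.frame(dropped = drop_nm, kept = keep_nm,
                 abs_r = Ca[idx[[1L]], idx[[2L]]])
    alive[drop_nm] <- FALSE
  }
  log <- new_pretreatment_log(
    dropped_correlated = if (length(decisions)) do.call(rbind, decisions)
                         else NULL,
    thresholds = list(r_threshold = r_threshold,
                      use_activity_tiebreak = use_activity_tiebreak))
  out <- if (all(alive)) dataset
         else ds_subset(dataset, cols = names(alive)[alive])
  list(dataset = out, log = log)
}

#' Fit column normalization parameters on the training partition
#'
#' Records per-descriptor minimum and maximum of the *training* data.
#' Two variants of the same affine map are provided: `"paper"` computes
#' `(X - Xmax)/(Xmax - Xmin)` (training columns land in `[-1, 0]`), and
#' `"minmax"` the conventional `(X - Xmin)/(Xmax - Xmin)` (`[0, 1]`). The
#' two differ by the constant 1 per column, so correlations and every
#' downstream R2/Q2 statistic are identical under either.
#'
#' @param train training [qsar_dataset()].
#' @param variant `"paper"` (default) or `"minmax"`.
#' @return An object of class `normalization_params`.
#' @export
fit_normalizer <- function(train, variant = c("paper", "minmax")) {
  variant <- match.arg(variant)
  stopifnot(inherits(train, "qsar_dataset"))
  xmin <- apply(train$X, 2L, min)
  xmax <- apply(train$X, 2L, max)
  bad <- colnames(train$X)[xmax <= xmin]
  if (length(bad))
    stop_named("constant column(s) reached the normalizer: %s",
               paste(bad, collapse = ", "))
  structure(list(names = colnames(train$X), xmin = xmin, xmax = xmax,
                 variant = variant),
            class = "normalization_params")
}

#' Apply fitted normalization to a dataset
#'
#' Uses the training-set parameters; values of a test partition may fall
#' outside the nominal interval and are deliberately not clipped.
#'
#' @param dataset a [qsar_dataset()] whose descriptors are all covered by
#'   `params`.
#' @param params a [fit_normalizer()] result.
#' @return The normalized `qsar_dataset`.
#' @export
apply_normalizer <- function(dataset, params) {
  stopifnot(inherits(dataset, "qsar_dataset"),
            inherits(params, "normalization_params"))
  missing <- setdiff(colnames(dataset$X), params$names)
  if (length(missing))
    stop_named("no normalization parameters for column(s): %s",
               paste(missing, collapse = ", "))
  nm <- colnames(dataset$X)
  lo <- params$xmin[match(nm, params$names)]
  hi <- params$xmax[match(nm, params$names)]
  ref <- if (params$variant == "paper") hi else lo
  Xn <- sweep(dataset$X, 2L, ref, "-")
  Xn <- sweep(Xn, 2L, hi - lo, "/")
  qsar_dataset(dataset$ids, Xn, dataset$y, dataset$activity_name)
}
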