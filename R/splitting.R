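# Kennard-Stone training/test division and descriptive statistics of an
# activity vector (spreadsheet-convention skewness/kurtosis).

#' Kennard-Stone training/test split
#'
#' Classic maximin selection on Euclidean distance in descriptor space:
#' the two mutually farthest compounds seed the training set, then the
#' compound whose minimum distance to the already-selected set is largest
#' is added until `n_train` compounds are selected. Every tie is broken by
#' the lowest row index, so the split is deterministic. Run it on
#' normalized descriptors so no single column dominates the metric; a
#' message is emitted when the data look unnormalized.
#'
#' @param dataset a [qsar_dataset()].
#' @param n_train number of training compounds, `2 <= n_train <= n`.
#' @param quiet suppress the normalization hint.
#' @return An object of class `split_result`: `train_ids` and `test_ids`
#'   (test in original dataset order), `selection_order` (the pick
#'   sequence, starting with the maximally distant pair), and
#'   `distance_metric`.
#' @export
kennard_stone_split <- function(dataset, n_train, quiet = FALSE) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  n <- length(dataset$ids)
  if (n_train < 2L || n_train > n)
    stop_named("n_train must be in [2, %d], got %s", n, n_train)
  rng <- range(apply(dataset$X, 2L, function(col) diff(range(col))))
  if (!quiet && rng[2L] > 10 * max(rng[1L], .Machine$double.eps))
    message("kennard_stone_split: descriptor column ranges differ by >10x; ",
            "consider normalizing first")
  D <- as.matrix(stats::dist(dataset$X))
  # seed pair: maximum distance, ties -> lexicographically smallest (i, j)
  m <- max(D)
  cand <- which(D == m, arr.ind = TRUE)
  cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
  cand <- cand[order(cand[, 1L], cand[, 2L])[1L], ]
  sel <- c(cand[[1L]], cand[[2L]])
  if (nrow(unique(dataset$X)) < n && !quiet)
    message("kennard_stone_split: duplicate descriptor rows present; ",
            "ties resolved by row index")
  while (length(sel) < n_train) {
    remaining <- setdiff(seq_len(n), sel)
    mind <- apply(D[remaining, sel, drop = FALSE], 1L, min)
    sel <- c(sel, remaining[which.max(mind)])  # which.max: first max wins
  }
  structure(list(train_ids = dataset$ids[sel],
                 test_ids = dataset$ids[setdiff(seq_len(n), sel)],
                 selection_order = dataset$ids[sel],
                 distance_metric = "euclidean"),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d train / %d test (%s distance)\n",
              length(x$train_ids), length(x$test_ids), x$distance_metric))
  invisible(x)
}

#' Descriptive statistics of an activity vector
#'
#' The eleven statistics of a spreadsheet-style descriptive table: n,
#' mean, standard error of the mean, median, sample SD, sample variance,
#' bias-corrected excess kurtosis, bias-corrected skewness, range, min,
#' max. Skewness requires `n >= 3` and kurtosis `n >= 4`; for a constant
#' vector both are reported as 0 with attribute `"degenerate" = TRUE`.
#'
#' @param values numeric vector, `length >= 2`.
#' @return An object of class `descriptive_stats` (a named list).
#' @examples
#' describe_activity(c(5.1, 6.2, 7.3, 8.4))
#' @export
describe_activity <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop_named("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  degenerate <- s == 0
  z3 <- if (s > 0) sum(((values - m) / s)^3) else NA_real_
  z4 <- if (s > 0) sum(((values - m) / s)^4) else NA_real_
  skew <- if (degenerate) 0
          else if (n >= 3L) n / ((n - 1) * (n - 2)) * z3
          else NA_real_
  kurt <- if (degenerate) 0
          else if (n >= 4L)
            n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * z4 -
              3 * (n - 1)^2 / ((n - 2) * (n - 3))
          else NA_real_
  out <- list(n = n, mean = m, standard_error = s / sqrt(n),
              median = stats::median(values), standard_deviation = s,
              sample_variance = s^2, kurtosis = kurt, skewness = skew,
              range = max(values) - min(values),
              minimum = min(values), maximum = max(values))
  structure(out, degenerate = degenerate, class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, digits = 3, ...) {
  cat("<descriptive_stats>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm,
                if (is.na(x[[nm]])) "NA" else format(round(x[[nm]], digits))))
  invisible(x)
}
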