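#' Specification for a synthetic descriptor/activity dataset
#'
#' Describes the stated world the generator emulates: a small congeneric
#' inhibitor series (default 50 compounds, activities on the pKi scale
#' roughly 4.5-9.6), a large descriptor pool (default 300) containing
#' correlated blocks (one latent factor per block, pairwise correlation
#' `block_correlation`) and near-constant columns, and a sparse linear
#' ground truth: activity = intercept + X[, support] %*% beta + N(0,
#' noise_sd). The default coefficients give a signal SD near 1.07 pKi
#' units, which with `noise_sd = 0.32` reproduces the activity spread
#' (SD ~ 1.1) and attainable fit quality (R2 ~ 0.92) of a typical small
#' QSAR series.
#'
#' Column layout: the correlated blocks occupy the first
#' `n_correlated_blocks * block_size` columns, independent N(0,1) columns
#' follow, and the `n_near_constant` near-constant columns (constant plus
#' jitter of SD 1e-9, food for the variance filter) come last.
#'
#' @param n_compounds number of compounds (default 50).
#' @param n_descriptors total descriptor pool size (default 300).
#' @param true_support indices of the truly active descriptors; default:
#'   three block members (one each from blocks 1-3) and the first three
#'   independent columns.
#' @param true_coefficients coefficients on the support, same length.
#' @param intercept intercept of the latent linear model (pKi units).
#' @param noise_sd SD of the additive Gaussian noise (pKi units).
#' @param n_correlated_blocks,block_size number and size of correlated
#'   descriptor blocks.
#' @param block_correlation pairwise within-block correlation, in [0, 1).
#' @param n_near_constant number of near-constant columns.
#' @param activity_range_target approximate (min, max) of the generated
#'   activities; the latent activity is mapped affinely onto this range
#'   using its theoretical mean and SD (see Details).
#' @param seed integer seed; the same spec yields identical data.
#' @details The affine rescaling is computed from the model's *population*
#'   moments (mean `intercept`, variance `beta' Sigma beta + noise_sd^2`),
#'   mapping mean +/- 2.25 SD onto the target range (2.25 SD is about the
#'   expected extreme of 50 normal draws). Using population rather than
#'   realized moments keeps the ground-truth coefficient transformation
#'   independent of the random draw.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 50, n_descriptors = 300,
                           true_support = NULL, true_coefficients = NULL,
                           intercept = 6.94, noise_sd = 0.32,
                           n_correlated_blocks = 5, block_size = 8,
                           block_correlation = 0.7, n_near_constant = 10,
                           activity_range_target = c(4.5, 9.6), seed = 1) {
  n_block_cols <- n_correlated_blocks * block_size
  n_free <- n_descriptors - n_block_cols - n_near_constant
  if (n_free < 0)
    stop_named("n_descriptors too small for the requested blocks and near-constant columns")
  if (is.null(true_support)) {
    blocks <- head(seq(1L, by = block_size, length.out = n_correlated_blocks), 3L)
    free <- head(n_block_cols + seq_len(max(n_free, 0L)), 3L)
    true_support <- c(blocks, free)
  }
  if (is.null(true_coefficients))
    true_coefficients <- c(0.45, 0.40, 0.45, 0.35, -0.55, 0.40)[
      seq_along(true_support)]
  true_support <- as.integer(true_support)
  if (anyDuplicated(true_support) || any(true_support < 1L) ||
      any(true_support > n_descriptors))
    stop_named("true_support indices must be distinct and within 1..n_descriptors")
  if (max(true_support) > n_descriptors - n_near_constant)
    stop_named("true_support must not hit a near-constant column")
  if (length(true_coefficients) != length(true_support))
    stop_named("true_coefficients must align with true_support")
  stopifnot(noise_sd >= 0, block_correlation >= 0, block_correlation < 1,
            length(activity_range_target) == 2,
            diff(activity_range_target) > 0)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 true_support = true_support,
                 true_coefficients = as.numeric(true_coefficients),
                 intercept = intercept, noise_sd = noise_sd,
                 n_correlated_blocks = as.integer(n_correlated_blocks),
                 block_size = as.integer(block_size),
                 block_correlation = block_correlation,
                 n_near_constant = as.integer(n_near_constant),
                 activity_range_target = activity_range_target,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Population covariance between two support columns under the block design.
support_covariance <- function(spec) {
  k <- length(spec$true_support)
  S <- diag(k)
  n_block_cols <- spec$n_correlated_blocks * spec$block_size
  block_of <- function(j) if (j <= n_block_cols)
    (j - 1L) %/% spec$block_size else NA_integer_
  b <- vapply(spec$true_support, block_of, 0L)
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j && !is.na(b[i]) && !is.na(b[j]) && b[i] == b[j])
      S[i, j] <- spec$block_correlation
  S
}

# Affine map (a, b) applied to the latent activity: y = a + b * y_raw.
activity_affine_map <- function(spec) {
  S <- support_covariance(spec)
  v <- drop(t(spec$true_coefficients) %*% S %*% spec$true_coefficients) +
    spec$noise_sd^2
  mu <- spec$intercept
  z <- 2.25
  b <- diff(spec$activity_range_target) / (2 * z * sqrt(v))
  a <- mean(spec$activity_range_target) - b * mu
  list(a = a, b = b, sd_theoretical = b * sqrt(v))
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws a descriptor matrix with the block structure described in
#' [synthetic_spec()], builds the activity from the sparse linear truth
#' plus Gaussian noise, and rescales it onto the target pKi range. The
#' returned ground truth is expressed on the *rescaled* activity scale, so
#' refitting the support on noise-free data recovers it exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `dataset` (a [qsar_dataset()]),
#'   `truth` (an `mlr_model` holding the rescaled intercept and support
#'   coefficients, plus attributes `noise_sd` and `support` names), and
#'   `spec`.
#' @examples
#' gen <- generate_dataset(synthetic_spec(seed = 7))
#' gen$dataset
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_compounds; K <- spec$n_descriptors
  nb <- spec$n_correlated_blocks; bs <- spec$block_size
  n_block_cols <- nb * bs
  n_free <- K - n_block_cols - spec$n_near_constant
  rho <- spec$block_correlation
  width <- max(3L, nchar(as.character(K)))
  names_all <- sprintf(paste0("D%0", width, "d"), seq_len(K))

  with_seed(spec$seed, {
    X <- matrix(NA_real_, n, K, dimnames = list(NULL, names_all))
    for (b in seq_len(nb)) {
      f <- rnorm(n)
      cols <- (b - 1L) * bs + seq_len(bs)
      eps <- matrix(rnorm(n * bs), n, bs)
      X[, cols] <- sqrt(rho) * f + sqrt(1 - rho) * eps
    }
    if (n_free > 0L)
      X[, n_block_cols + seq_len(n_free)] <- matrix(rnorm(n * n_free), n, n_free)
    if (spec$n_near_constant > 0L) {
      cols <- K - spec$n_near_constant + seq_len(spec$n_near_constant)
      levels <- runif(spec$n_near_constant, 0, 10)
      X[, cols] <- rep(levels, each = n) +
        matrix(rnorm(n * spec$n_near_constant, sd = 1e-9), n)
    }
    y_raw <- spec$intercept +
      drop(X[, spec$true_support, drop = FALSE] %*% spec$true_coefficients) +
      rnorm(n, sd = spec$noise_sd)
    map <- activity_affine_map(spec)
    y <- map$a + map$b * y_raw

    coefs <- map$b * spec$true_coefficients
    names(coefs) <- names_all[spec$true_support]
    truth <- new_mlr_model(map$a + map$b * spec$intercept, coefs, n)
    attr(truth, "noise_sd") <- map$b * spec$noise_sd
    attr(truth, "support") <- names_all[spec$true_support]

    ids <- sprintf("CPD%03d", seq_len(n))
    list(dataset = qsar_dataset(ids, X, y), truth = truth, spec = spec)
  })
}
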